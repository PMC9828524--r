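#' Discretised class grid of biomass-specific rates
#'
#' The biomass population is divided into 10 classes of biomass-specific
#' growth rate \eqn{\mu_i = Y_{XS} q_S (2i-1)/20} (1/h) or substrate
#' uptake rate \eqn{q_i = q_S (2i-1)/20} (g/g/h), i = 1..10, with class
#' widths \eqn{\Delta\mu = Y_{XS} q_S/10} and \eqn{\Delta q = q_S/10} and
#' adaptation time-scales \eqn{T_X} (growth, slow) and \eqn{T_S} (uptake,
#' fast).  The local equilibrium rate toward which the population drifts
#' is \eqn{Y_{XS} q_S S/(S+K_S)} (constant-yield, no decay) for growth
#' and \eqn{q_S S/(S+K_S)} for uptake.
#'
#' @param kind \code{"growth"} or \code{"uptake"}.
#' @param params a \code{\link{kinetic_params}}.
#' @param n_classes number of classes (default 10).
#' @return Object of class \code{"class_grid"}: \code{rates},
#'   \code{width}, \code{T_adapt}, and \code{equilibrium(S)}.
#' @examples
#' class_grid("growth")$rates[1]   # 0.025 1/h
#' class_grid("uptake")$rates[2]   # 0.15 g/g/h
#' @export
class_grid <- function(kind = c("growth", "uptake"),
                       params = kinetic_params(), n_classes = 10L) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "kinetic_params"), n_classes >= 2L)
  top <- if (kind == "growth") params$YXS * params$qS else params$qS
  rates <- top * (2 * seq_len(n_classes) - 1) / (2 * n_classes)
  width <- if (kind == "growth") params$Dmu else params$Dq
  T_adapt <- if (kind == "growth") params$TX else params$TS
  eq <- function(S) top * S / (S + params$KS)
  structure(list(kind = kind, rates = rates, width = width,
                 T_adapt = T_adapt, equilibrium = eq,
                 n_classes = as.integer(n_classes)),
            class = "class_grid")
}

#' Adaptation transfer rate of one biomass class
#'
#' Signed transfer rate (g/L/h) of biomass out of class i:
#' \eqn{(X_i/\Delta\mu)(1/T_X + \mu_i)(\mu_{eq}(S) - \mu_i)}, positive
#' rates moving biomass to class i+1 and negative to class i-1 (pure
#' donor-class upwinding, which keeps class concentrations
#' non-negative).  Transfers beyond the grid ends are clamped to zero.
#'
#' @param Xi biomass concentration in class i (g/L).
#' @param grid a \code{\link{class_grid}}.
#' @param i class index (1-based).
#' @param S_local local substrate concentration (g/L).
#' @return Transfer rate (g/L/h); sign gives the direction.
#' @export
adaptation_rate <- function(Xi, grid, i, S_local) {
  stopifnot(inherits(grid, "class_grid"))
  if (i < 1L || i > grid$n_classes) stop("class index out of range")
  v <- (1 / grid$T_adapt + grid$rates[i]) *
    (grid$equilibrium(S_local) - grid$rates[i]) / grid$width
  rate <- v * Xi
  if ((i == grid$n_classes && rate > 0) || (i == 1L && rate < 0)) 0 else rate
}

# Sparse generator of the coupled spatial-transport + class-transfer
# system, ordered class-fastest: unknown (c-1)*K + i for compartment c,
# class i.  Linear in X for a frozen substrate field.
population_operator <- function(op, S_field, grid) {
  K <- grid$n_classes
  n <- length(op$volumes)
  Ah <- as(op$A * 3600, "TsparseMatrix")   # 1/h
  ii <- (Ah@i) * K; jj <- (Ah@j) * K       # 0-based block offsets
  ti <- as.vector(outer(seq_len(K), ii, `+`))
  tj <- as.vector(outer(seq_len(K), jj, `+`))
  tx <- rep(Ah@x, each = K)
  # class-transfer drift velocities per compartment
  eq <- grid$equilibrium(S_field)
  for (c_ in seq_len(n)) {
    v <- (1 / grid$T_adapt + grid$rates) * (eq[c_] - grid$rates) / grid$width
    v[K] <- min(v[K], 0); v[1] <- max(v[1], 0)   # boundary clamps
    base <- (c_ - 1L) * K
    up <- which(v > 0); dn <- which(v < 0)
    if (length(up)) {
      ti <- c(ti, base + up, base + up + 1L)
      tj <- c(tj, base + up, base + up)
      tx <- c(tx, -v[up], v[up])
    }
    if (length(dn)) {
      ti <- c(ti, base + dn, base + dn - 1L)
      tj <- c(tj, base + dn, base + dn)
      tx <- c(tx, v[dn], -v[dn])
    }
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n * K, n * K))
}

#' Steady population distribution over a frozen substrate field
#'
#' Solves the coupled steady state of the class concentrations under
#' spatial transport (the same operator applied to every class) and
#' inter-class adaptation transfer, by backward-Euler pseudo-time with a
#' factorised sparse solve (the scheme conserves the per-compartment
#' total biomass and non-negativity exactly).  The substrate field is
#' frozen (one-way coupling).  Initialised with all biomass split
#' between the two classes bracketing the ideal-reactor equilibrium
#' rate.
#'
#' @param op a \code{\link{transport_operator}}.
#' @param S_field substrate concentrations (g/L, per compartment) or a
#'   \code{\link{solve_substrate_field}} result.
#' @param grid a \code{\link{class_grid}}.
#' @param params a \code{\link{kinetic_params}}.
#' @param tol RMS steady-state residual tolerance (g/L/h).
#' @return Object of class \code{"population_state"}: matrix \code{X}
#'   (compartments x classes, g/L), plus \code{grid} and
#'   \code{volumes}.
#' @export
solve_population_field <- function(op, S_field, grid = class_grid("growth"),
                                   params = kinetic_params(), tol = 1e-9) {
  if (inherits(S_field, "steady_field")) S_field <- S_field$S
  n <- length(op$volumes); K <- grid$n_classes
  stopifnot(length(S_field) == n)
  M <- population_operator(op, S_field, grid)
  # initial: biomass in the two classes bracketing the ideal equilibrium
  eq0 <- grid$equilibrium(ideal_reactor_state(params)$S)
  lo <- max(1L, min(K - 1L, findInterval(eq0, grid$rates)))
  x0 <- matrix(0, n, K)
  x0[, lo] <- params$X / 2; x0[, lo + 1L] <- params$X / 2
  x <- as.vector(t(x0))
  dt <- 50  # h; large pseudo-step = inverse iteration toward the kernel
  Msys <- Matrix::Diagonal(n * K) - dt * M
  lu <- Matrix::lu(Msys)
  for (it in 1:500) {
    x_new <- as.numeric(Matrix::solve(lu, x))
    res <- sqrt(mean(as.numeric(M %*% x_new)^2))
    x <- x_new
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf("population balance did not reach steady state (residual %.3g)",
                 res))
  X <- matrix(x, n, K, byrow = TRUE)
  structure(list(X = X, grid = grid, volumes = op$volumes,
                 residual = res, total = params$X),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population state: %d compartments x %d classes>\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Population summary: class means, spreads and averaged specific rate
#'
#' Per-class volume-weighted mean concentration and volumetric standard
#' deviation (the error bars of a class-distribution bar chart), and the
#' population-averaged specific rate
#' \eqn{\sum_i \langle X_i\rangle \mu_i / X}.
#'
#' @param state a \code{\link{solve_population_field}} result, or a
#'   numeric matrix (compartments x classes) with \code{volumes} given.
#' @param grid a \code{\link{class_grid}} (taken from \code{state} when
#'   available).
#' @param volumes compartment volumes (taken from \code{state}).
#' @return List with \code{class_mean}, \code{class_sd},
#'   \code{mean_rate}.
#' @export
population_summary <- function(state, grid = NULL, volumes = NULL) {
  if (inherits(state, "population_state")) {
    X <- state$X; grid <- state$grid; volumes <- state$volumes
  } else X <- state
  stopifnot(!is.null(grid), !is.null(volumes), nrow(X) == length(volumes))
  w <- volumes / sum(volumes)
  cm <- as.numeric(w %*% X)
  csd <- sqrt(pmax(as.numeric(w %*% X^2) - cm^2, 0))
  list(class_mean = cm, class_sd = csd,
       mean_rate = sum(cm * grid$rates) / sum(cm))
}
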