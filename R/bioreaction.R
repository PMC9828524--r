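#' Ideal homogeneous reactor reference state
#'
#' Pseudo-steady substrate and dissolved-oxygen concentrations of a
#' perfectly mixed fed-batch reactor.  The substrate balance
#' \eqn{q_S X S/(S+K_S) = F} gives \eqn{S^* = K_S \phi/(1-\phi)} with
#' \eqn{\phi = F/(q_S X)}; the oxygen balance equates transfer
#' \eqn{k_La (O_e - O)} with consumption
#' \eqn{1000\, Y_{OS} F\, O/(O+K_O)} (the factor 1000 bridges the g/L
#' substrate and mg/L oxygen unit scales) and is solved by a bracketed
#' root find to 1e-10.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param F substrate feed rate (g/L/h); defaults to \code{params$F}.
#' @return List with \code{S} (g/L) and \code{O} (mg/L).
#' @examples
#' s <- ideal_reactor_state(kinetic_params())
#' c(S_mg = s$S * 1000, O = s$O)  # 16.7 mg/L, 0.113 mg/L
#' @export
ideal_reactor_state <- function(params = kinetic_params(), F = params$F) {
  stopifnot(inherits(params, "kinetic_params"))
  if (F < 0) stop("'F' must be non-negative")
  if (F == 0) return(list(S = 0, O = params$Oe))
  cap <- params$qS * params$X
  if (F >= cap)
    stop(sprintf("infeasible feed: F = %g g/L/h >= qS X = %g g/L/h", F, cap))
  phi <- F / cap
  S <- params$KS * phi / (1 - phi)
  f <- function(O) params$kLa * (params$Oe - O) -
    1000 * params$YOS * F * O / (O + params$KO)
  O <- stats::uniroot(f, c(1e-12, params$Oe), tol = 1e-10)$root
  list(S = S, O = O)
}

#' Oxygen solubility from Henry's law at mid-height
#'
#' Equilibrium dissolved-oxygen concentration at the oxygen partial
#' pressure (21 percent of air) prevailing at the reactor's middle
#' height: the head pressure plus the hydrostatic pressure of the
#' ungassed liquid column at half its height (density 994 kg/m^3),
#' converted to a gas-phase concentration by the ideal gas law and
#' multiplied by the dimensionless Henry constant
#' (liquid/gas concentration ratio, 0.0266 for oxygen at 35 C).
#'
#' @param spec a \code{\link{reactor_spec}} (supplies height and gas
#'   holdup).
#' @param head_pressure head-space pressure (Pa), default 1.5 bar.
#' @param temperature K, default 308.15.
#' @param henry dimensionless Henry constant, default 0.0266.
#' @param o2_fraction oxygen mole fraction of the gas, default 0.21.
#' @param rho liquid density (kg/m^3), default 994.
#' @return Oe in mg/L.
#' @examples
#' oxygen_solubility(reactor_catalog("R4"))  # 12.69 mg/L
#' @export
oxygen_solubility <- function(spec, head_pressure = 1.5e5,
                              temperature = 308.15, henry = 0.0266,
                              o2_fraction = 0.21, rho = 994) {
  stopifnot(inherits(spec, "reactor_spec"), head_pressure > 0,
            temperature > 0, henry >= 0)
  h_half <- spec$height * (1 - spec$gas_holdup) / 2
  p_o2 <- o2_fraction * (head_pressure + rho * 9.81 * h_half)
  henry * p_o2 / (8.314 * temperature) * 32   # mol/m^3 * g/mol = mg/L
}

# Backward-Euler pseudo-time march to a nonlinear steady state.
# Solves (I/dt - J) step = R(x) with a sparse LU at each iteration;
# the step doubles on residual decrease and halves otherwise, so the
# fixed point of the prescribed constant-step scheme is preserved.
pseudo_time_solve <- function(residual, jacobian, x0, tol, clamp = identity,
                              dt0 = 1e-3, dt_max = 1e6, max_iter = 1000L) {
  x <- clamp(x0)
  r <- residual(x)
  rn <- sqrt(mean(r^2))
  dt <- dt0
  n <- length(x)
  I <- Matrix::Diagonal(n)
  for (it in seq_len(max_iter)) {
    if (rn < tol) return(list(x = x, residual = rn, iterations = it - 1L))
    J <- jacobian(x)
    step <- tryCatch(
      as.numeric(Matrix::solve(I / dt - J, r)),
      error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) { dt <- dt / 2; next }
    x_new <- clamp(x + step)
    r_new <- residual(x_new)
    rn_new <- sqrt(mean(r_new^2))
    if (is.finite(rn_new) && (rn_new < rn || dt <= 1e-12)) {
      x <- x_new; r <- r_new; rn <- rn_new
      dt <- min(dt * 2, dt_max)
    } else {
      dt <- dt / 2
      if (dt < 1e-15)
        stop("pseudo-time iteration stagnated; try a smaller initial step")
    }
  }
  if (rn >= tol)
    stop(sprintf("steady-state solve did not converge: residual %.3g > %.3g",
                 rn, tol))
  list(x = x, residual = rn, iterations = max_iter)
}

feed_source <- function(op, feed, F) {
  V <- op$volumes
  f <- numeric(length(V))
  f[feed$index] <- feed$weight * F * sum(V) / V[feed$index]
  f
}

#' Fed-batch pseudo-steady substrate field
#'
#' Solves \eqn{A S + f - q_S X S/(S+K_S) = 0} per compartment, where A is
#' the transport operator (converted to 1/h) and f the volumetric feed
#' source: each feed point delivers its weight share of the overall feed
#' rate F (g/L/h referred to the total volume), concentrated into its
#' compartment.  Backward-Euler pseudo-time with the analytic Jacobian
#' and sparse LU solves, initialised at the ideal-reactor concentration;
#' converged when the RMS residual falls below \code{1e-10 F}.  At
#' steady state the volume-weighted mean uptake equals the feed rate
#' exactly (mass balance closure).
#'
#' @param op a \code{\link{transport_operator}}.
#' @param feed feed compartments and weights.
#' @param params a \code{\link{kinetic_params}}.
#' @param F feed rate (g/L/h), default \code{params$F}.
#' @return Object of class \code{"steady_field"}: list with \code{S}
#'   (g/L per compartment), \code{source}, solver diagnostics.
#' @export
solve_substrate_field <- function(op, feed, params = kinetic_params(),
                                  F = params$F) {
  stopifnot(inherits(op, "transport_operator"))
  ideal <- ideal_reactor_state(params, F)
  Ah <- op$A * 3600                      # 1/s -> 1/h
  f <- feed_source(op, feed, F)
  qX <- params$qS * params$X; KS <- params$KS
  res <- function(S) as.numeric(Ah %*% S) + f - qX * S / (S + KS)
  jac <- function(S) Ah - Matrix::Diagonal(x = qX * KS / (S + KS)^2)
  sol <- pseudo_time_solve(res, jac, rep(ideal$S, length(op$volumes)),
                           tol = 1e-10 * F,
                           clamp = function(x) pmax(x, 1e-15))
  structure(list(S = sol$x, source = f, params = params, F = F,
                 ideal = ideal, residual = sol$residual,
                 iterations = sol$iterations, volumes = op$volumes),
            class = "steady_field")
}

#' Dissolved-oxygen field over a frozen substrate field
#'
#' Solves \eqn{A O + k_La(O_e - O) - 1000 Y_{OS}\, r_S\, O/(O+K_O) = 0}
#' with \eqn{r_S = q_S X S/(S+K_S)} from a converged substrate field
#' (one-way coupling; the factor 1000 converts the g/L/h substrate rate
#' to the mg/L oxygen scale).  The aerobically respired proportion of
#' substrate is \eqn{O/(O+K_O)}.
#'
#' @param op a \code{\link{transport_operator}}.
#' @param substrate a \code{\link{solve_substrate_field}} result (or a
#'   numeric S vector, g/L).
#' @param params a \code{\link{kinetic_params}}.
#' @return Numeric vector O (mg/L per compartment), in (0, Oe].
#' @export
solve_oxygen_field <- function(op, substrate, params = kinetic_params()) {
  S <- if (inherits(substrate, "steady_field")) substrate$S else substrate
  stopifnot(length(S) == length(op$volumes), all(S >= 0))
  Ah <- op$A * 3600
  rS <- params$qS * params$X * S / (S + params$KS)
  kLa <- params$kLa; Oe <- params$Oe; KO <- params$KO
  cons <- 1000 * params$YOS * rS
  res <- function(O) as.numeric(Ah %*% O) + kLa * (Oe - O) -
    cons * O / (O + KO)
  jac <- function(O) Ah - Matrix::Diagonal(x = kLa + cons * KO / (O + KO)^2)
  O0 <- tryCatch(ideal_reactor_state(params)$O, error = function(e) Oe / 2)
  sol <- pseudo_time_solve(res, jac, rep(O0, length(S)),
                           tol = 1e-10 * kLa * Oe,
                           clamp = function(x) pmin(pmax(x, 1e-15), Oe))
  sol$x
}

#' Substrate-consumption time-scale and instantaneous biomass yield
#'
#' From a substrate field: the first-order time-scale
#' \eqn{\tau_S = (S+K_S)/(q_S X)} (h) of substrate consumption, and the
#' instantaneous yield \eqn{y_{XS} = Y_{XS} - (q_d/q_S)(1 + K_S/S)}
#' (g/g), which accounts for first-order biomass decay and may go
#' negative where the substrate is strongly depleted.
#'
#' @param S substrate field (g/L), strictly positive.
#' @param params a \code{\link{kinetic_params}}.
#' @return List with \code{tau_S} (h) and \code{y_XS} (g/g).
#' @export
derived_fields <- function(S, params = kinetic_params()) {
  if (inherits(S, "steady_field")) S <- S$S
  if (any(S <= 0)) stop("'S' must be strictly positive")
  list(tau_S = (S + params$KS) / (params$qS * params$X),
       y_XS = params$YXS - (params$qd / params$qS) * (1 + params$KS / S))
}

#' Volumetric statistics of a concentration field
#'
#' Volume-weighted mean, standard deviation and relative standard
#' deviation, together with the Monod concavity diagnostics: the
#' averaged Monod factor \eqn{\langle S/(S+K_S)\rangle}, the Monod factor
#' of the mean \eqn{\langle S\rangle/(\langle S\rangle+K_S)}, and the
#' second-order Taylor correction
#' \eqn{K_S \sigma_S^2/(\langle S\rangle+K_S)^3}.  By Jensen's
#' inequality the averaged factor never exceeds the factor of the mean:
#' heterogeneity always lowers the overall Monod-type consumption rate.
#'
#' @param field per-compartment values.
#' @param volumes compartment volumes.
#' @param KS affinity constant for the Monod diagnostics (same units as
#'   \code{field}); default 0.025.
#' @return List of class \code{"field_stats"}.
#' @export
field_statistics <- function(field, volumes, KS = 0.025) {
  stopifnot(length(field) == length(volumes), all(volumes > 0))
  w <- volumes / sum(volumes)
  m <- sum(w * field)
  v <- sum(w * (field - m)^2)
  s <- sqrt(v)
  structure(list(mean = m, sd = s, rel_sd = s / m,
                 averaged_monod = sum(w * field / (field + KS)),
                 monod_of_mean = m / (m + KS),
                 taylor_correction = KS * v / (m + KS)^3),
            class = "field_stats")
}

#' @export
print.field_stats <- function(x, ...) {
  cat(sprintf("<field stats: mean %.4g, sd %.4g (%.1f%%)>\n",
              x$mean, x$sd, 100 * x$rel_sd))
  invisible(x)
}
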