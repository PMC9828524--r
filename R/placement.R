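#' Roots of Bessel functions of the first kind
#'
#' Computes the first \code{n} strictly positive roots of the zeroth- or
#' first-order Bessel function of the first kind.  These roots govern the
#' radial eigenmodes of turbulent mixing in a cylindrical vessel: the roots
#' of \eqn{J_1} are the radial decay-rate constants' eigenvalues (symmetry
#' boundary at the wall), and the roots of \eqn{J_0} locate the radial feed
#' coordinates that annihilate the slowest modes.
#'
#' Roots are bracketed on a grid built from the large-argument asymptotics
#' of the Bessel zeros, refined with \code{\link[stats]{uniroot}}, and
#' polished with two Newton steps (using \eqn{J_0' = -J_1} and
#' \eqn{J_1' = J_0 - J_1(x)/x}) so that \eqn{|J(\mathrm{root})| <
#' 10^{-12}}.
#'
#' @param kind \code{"J0"} or \code{"J1"}.
#' @param n number of roots (positive integer).
#' @return Numeric vector of the first \code{n} positive roots, strictly
#'   increasing.
#' @examples
#' bessel_roots("J0", 2)  # 2.404826 5.520078
#' bessel_roots("J1", 2)  # 3.831706 7.015587
#' @export
bessel_roots <- function(kind = c("J0", "J1"), n) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  nu <- if (kind == "J0") 0 else 1
  f <- function(x) besselJ(x, nu)
  # asymptotic zero locations: J0 ~ (m - 1/4) pi, J1 ~ (m + 1/4) pi
  guess <- (seq_len(n) + if (nu == 0) -0.25 else 0.25) * pi
  roots <- numeric(n)
  for (m in seq_len(n)) {
    lo <- if (m == 1) max(0.1, guess[1] - 1.5) else roots[m - 1] + 0.5
    hi <- guess[m] + 1.5
    # walk a fine grid to find the sign change (robust for small roots)
    xs <- seq(lo, hi, length.out = 64L)
    fs <- f(xs)
    i <- which(fs[-length(fs)] * fs[-1] <= 0)[1]
    if (is.na(i)) stop("failed to bracket Bessel root ", m)
    r <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root
    # Newton polish
    for (it in 1:2) {
      df <- if (nu == 0) -besselJ(r, 1) else besselJ(r, 0) - besselJ(r, 1) / r
      r <- r - f(r) / df
    }
    roots[m] <- r
  }
  roots
}

#' One-dimensional turbulent-diffusion mixing problem
#'
#' Describes a single insulated 1D domain (axial, radial, or tangential
#' slice of a cylindrical vessel) in which mixing of a pulse-fed substance
#' is modelled as turbulent diffusion.  The domain carries zero-gradient
#' (symmetry) boundaries, a turbulent diffusivity \code{d} that lumps all
#' transport, and the feed position whose eigen-series solution the other
#' placement functions evaluate.
#'
#' For the tangential dimension the feed sits at the sector middle
#' \eqn{\phi_0 = \Phi/2} (equivalent to a periodic domain) and the decay
#' rates depend on the evaluation radius \code{eval_radius}; only full
#' sectors \eqn{\Phi = 2\pi/k} with integer \eqn{k} are accepted.
#'
#' @param dimension one of \code{"axial"}, \code{"radial"},
#'   \code{"tangential"}.
#' @param size domain size: height H (m) for axial, radius R (m) for
#'   radial, sector angle \eqn{\Phi} (rad) for tangential.
#' @param diffusivity turbulent diffusivity d (m^2/s).
#' @param feed_position feed coordinate in domain units (for tangential it
#'   must equal \code{size/2}; defaults accordingly).
#' @param eval_radius radius r (m) at which tangential decay rates are
#'   evaluated (tangential only).
#' @param n_terms series truncation (default 50).  The truncated tail of
#'   the concentration series is bounded by
#'   \eqn{2\exp(-k_{n+1} t)/(1 - \exp(-(k_{n+2}-k_{n+1})t))}; 50 terms put
#'   this below 1e-8 for all times past the small-time cutoff
#'   \eqn{t > 0.2/k_1}.
#' @return An object of class \code{"diffusion1d"}.
#' @export
diffusion_problem <- function(dimension = c("axial", "radial", "tangential"),
                              size, diffusivity,
                              feed_position = if (dimension == "tangential") size / 2 else 0,
                              eval_radius = NULL, n_terms = 50L) {
  dimension <- match.arg(dimension)
  stopifnot(is.numeric(size), size > 0, is.numeric(diffusivity), diffusivity > 0,
            n_terms >= 1)
  if (feed_position < 0 || feed_position > size)
    stop("'feed_position' must lie in [0, size]")
  if (dimension == "tangential") {
    if (size > 2 * pi + 1e-12) stop("tangential sector must satisfy 0 < Phi <= 2*pi")
    k <- 2 * pi / size
    if (abs(k - round(k)) > 1e-8)
      stop("tangential sector must be 2*pi/k for integer k (symmetry boundaries)")
    if (is.null(eval_radius) || eval_radius <= 0)
      stop("tangential problems need a positive 'eval_radius'")
    if (abs(feed_position - size / 2) > 1e-12 * size)
      stop("tangential feed must sit at the sector middle Phi/2")
  }
  structure(list(dimension = dimension, size = size, d = diffusivity,
                 feed_position = feed_position, eval_radius = eval_radius,
                 n_terms = as.integer(n_terms)),
            class = "diffusion1d")
}

#' @export
print.diffusion1d <- function(x, ...) {
  cat("1D turbulent-diffusion problem (", x$dimension, ")\n", sep = "")
  cat("  size:", x$size, " diffusivity:", x$d,
      " feed at:", x$feed_position, " terms:", x$n_terms, "\n")
  invisible(x)
}

#' Pre-exponential coefficient of an eigen-series term
#'
#' Coefficient \eqn{A_m} of the m-th exponentially decaying term of the 1D
#' mixing series, evaluated at a measurement position.  Axial:
#' \eqn{2\cos(m\pi z_0/H)\cos(m\pi z/H)}; radial:
#' \eqn{J_0(\beta_m r_0/R) J_0(\beta_m r/R)/J_0(\beta_m)^2} with
#' \eqn{\beta_m} the m-th root of \eqn{J_1}; tangential (feed at sector
#' middle, only even modes survive): \eqn{2\cos(m\pi)\cos(2 m\pi\phi/\Phi)}.
#'
#' A centered axial feed (\eqn{z_0 = H/2}) zeroes every odd-m coefficient —
#' the basis of the centre-placement rule — and a radial feed at
#' \eqn{r_0/R = \alpha_1/\beta_1 \approx 0.628} zeroes the first radial
#' term.
#'
#' @param problem a \code{\link{diffusion_problem}}.
#' @param m term index (positive integer, vectorised).
#' @param eval_position measurement coordinate in domain units.
#' @return Dimensionless coefficient(s) \eqn{A_m}.
#' @export
preexponential <- function(problem, m, eval_position) {
  stopifnot(inherits(problem, "diffusion1d"), all(m >= 1), all(m == round(m)))
  if (any(eval_position < 0) || any(eval_position > problem$size))
    stop("'eval_position' outside the domain")
  L <- problem$size
  z0 <- problem$feed_position
  switch(problem$dimension,
    axial = 2 * cos(m * pi * z0 / L) * cos(m * pi * eval_position / L),
    radial = {
      beta <- bessel_roots("J1", max(m))[m]
      besselJ(beta * z0 / L, 0) * besselJ(beta * eval_position / L, 0) /
        besselJ(beta, 0)^2
    },
    tangential = 2 * cos(m * pi) * cos(2 * m * pi * eval_position / L))
}

#' First-order decay-rate constant of an eigen-series term
#'
#' Rate constant \eqn{k_m} (1/s) of the m-th series term: axial
#' \eqn{m^2\pi^2 d/H^2}; radial \eqn{\beta_m^2 d/R^2}; tangential
#' \eqn{4 m^2 \pi^2 d/(\Phi^2 r^2)} at the problem's evaluation radius.
#'
#' @inheritParams preexponential
#' @return Rate constant(s) in 1/time, strictly increasing in \code{m}.
#' @export
rate_constant <- function(problem, m) {
  stopifnot(inherits(problem, "diffusion1d"), all(m >= 1), all(m == round(m)))
  L <- problem$size
  switch(problem$dimension,
    axial = m^2 * pi^2 * problem$d / L^2,
    radial = bessel_roots("J1", max(m))[m]^2 * problem$d / L^2,
    tangential = 4 * m^2 * pi^2 * problem$d / (L^2 * problem$eval_radius^2))
}

#' Concentration eigen-series after a pulse feed
#'
#' Dimensionless concentration \eqn{u(x, t) = 1 + \sum_m A_m e^{-k_m t}},
#' truncated at the problem's \code{n_terms}.  The spatial mean of
#' \eqn{u} is exactly 1 at all times (the fluctuating modes integrate to
#' zero; radially with area weight \eqn{2\pi r\,dr}).
#'
#' @inheritParams preexponential
#' @param t time (scalar or vector, same units as 1/rate constant).
#' @return Matrix of u values, \code{length(eval_position)} rows by
#'   \code{length(t)} columns, dropped to a vector when either is scalar.
#' @export
concentration_series <- function(problem, eval_position, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  m <- seq_len(problem$n_terms)
  A <- outer(eval_position, m, function(x, mm) preexponential(problem, mm, x))
  k <- rate_constant(problem, m)
  u <- 1 + A %*% exp(-outer(k, t))
  if (length(t) == 1L || length(eval_position) == 1L) drop(u) else u
}

#' Closed-form standard deviation of the axial tracer field
#'
#' Volume-based mixing metric
#' \eqn{\sigma^2(t) = \sum_m 2\cos^2(m\pi z_0/H) e^{-2 k_m t}} (the spatial
#' mean square deviation of u from 1), truncated at \code{n_terms}.
#' Monotone non-increasing in t.
#'
#' @inheritParams preexponential
#' @param t time(s), non-negative.
#' @return \eqn{\sigma(t)} (dimensionless), vectorised over \code{t}.
#' @export
sigma_axial <- function(problem, t) {
  if (problem$dimension != "axial")
    stop("sigma_axial() supports axial problems only")
  if (any(t < 0)) stop("'t' must be non-negative")
  m <- seq_len(problem$n_terms)
  c2 <- 2 * cos(m * pi * problem$feed_position / problem$size)^2
  k <- rate_constant(problem, m)
  sqrt(colSums(c2 * exp(-2 * outer(k, t))))
}

#' Mixing time of the 1D axial model
#'
#' Time at which the tracer standard deviation \code{\link{sigma_axial}}
#' falls to \code{threshold} (default 5\%, the conventional 95\% mixing
#' time t95).  \eqn{\sigma} is monotone, so the crossing is unique; it is
#' bracketed on a geometric time grid and refined by bisection to 1e-8
#' relative tolerance.
#'
#' @inheritParams preexponential
#' @param threshold mixing threshold in (0, 1); default 0.05.
#' @return Mixing time t95 in the problem's time units.
#' @export
mixing_time_1d <- function(problem, threshold = 0.05) {
  if (problem$dimension != "axial")
    stop("mixing_time_1d() supports axial problems only")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)")
  k1 <- rate_constant(problem, 1)
  f <- function(t) sigma_axial(problem, t) - threshold
  # geometric bracket: sigma decays at least as fast as the slowest term
  hi <- 1 / k1
  while (f(hi) > 0) hi <- hi * 2
  lo <- hi / 2
  while (f(lo) < 0) { hi <- lo; lo <- lo / 2 }
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-8 * hi) break
  }
  0.5 * (lo + hi)
}

#' Optimal axial feed positions
#'
#' For N feed points, the positions \eqn{z_i/H = (2i-1)/(2N)} split the
#' height into N equal subdomains with a centred feed in each; the
#' limiting decay rate then scales as \eqn{N^2}.
#'
#' @param N number of axial feed points (positive integer).
#' @return Vector of N fractions of working height, strictly increasing.
#' @examples
#' optimal_axial_positions(4)  # 0.125 0.375 0.625 0.875
#' @export
optimal_axial_positions <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  (2 * seq_len(N) - 1) / (2 * N)
}

#' Optimal radial feed placement with weights
#'
#' For N radial feed coordinates the optima sit at
#' \eqn{r_i/R = \alpha_i/\beta_N} (\eqn{\alpha_i} the i-th root of
#' \eqn{J_0}, \eqn{\beta_N} the N-th root of \eqn{J_1}), which zeroes the
#' N-th radial mode for every feed ring.  The lower modes m < N are
#' annihilated by per-ring weights solving the linear system whose rows
#' are \eqn{J_0(\beta_m r_i/R)} (m = 1..N-1) plus a row of ones forcing
#' the weights to sum to 1.
#'
#' Tangential feed counts per ring are returned as the smallest integers
#' approximately proportional to the radii (\code{round(N * r_i / r_N)},
#' floored at 1), which keeps the tangential rate constants of the rings
#' approximately equal (equal perimeter per feed point).
#'
#' @param N number of radial coordinates (positive integer).
#' @return Object of class \code{"placement_plan"}: list with
#'   \code{radial_fractions}, \code{weights}, \code{tangential_counts},
#'   and the residual norm of the weight system.
#' @examples
#' optimal_radial_placement(1)$radial_fractions  # 0.6276
#' optimal_radial_placement(2)$weights           # 0.302 0.698
#' @export
optimal_radial_placement <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  alpha <- bessel_roots("J0", N)
  beta <- bessel_roots("J1", N)
  frac <- alpha / beta[N]
  if (N == 1) {
    w <- 1
    resid <- 0
  } else {
    M <- rbind(outer(beta[seq_len(N - 1)], frac,
                     function(b, r) besselJ(b * r, 0)),
               rep(1, N))
    rhs <- c(rep(0, N - 1), 1)
    w <- tryCatch(solve(M, rhs),
                  error = function(e) stop("weight system is singular: ",
                                           conditionMessage(e)))
    resid <- sqrt(sum((M %*% w - rhs)^2))
  }
  counts <- pmax(1L, as.integer(round(N * frac / frac[N])))
  structure(list(radial_fractions = frac, weights = as.numeric(w),
                 tangential_counts = counts, residual = resid),
            class = "placement_plan")
}

#' @export
print.placement_plan <- function(x, ...) {
  cat("Radial feed placement plan (", length(x$radial_fractions),
      " radius/radii)\n", sep = "")
  print(data.frame(r_over_R = round(x$radial_fractions, 4),
                   weight = round(x$weights, 4),
                   tangential_points = x$tangential_counts))
  invisible(x)
}

#' Theoretical fold-increase of the limiting mixing rate
#'
#' Placing N feed points at the optimal axial positions subdivides the
#' height into N centred-feed subdomains; the limiting rate constant
#' grows as \eqn{N^2} relative to a single centred feed, and by an extra
#' factor 4 relative to an end (top or bottom) feed, whose slowest mode a
#' centred feed eliminates.
#'
#' @param N number of axial feed points.
#' @param reference \code{"center_feed"} or \code{"end_feed"}.
#' @return Dimensionless fold-change of the limiting rate constant.
#' @examples
#' limiting_rate_multiplier(4, "end_feed")  # 64
#' @export
limiting_rate_multiplier <- function(N, reference = c("center_feed", "end_feed")) {
  if (!is.numeric(N) || any(N < 1) || any(N != round(N)))
    stop("'N' must be a positive integer")
  reference <- match.arg(reference)
  if (reference == "center_feed") N^2 else 4 * N^2
}

#' Scale-up equivalents of a mixing-rate improvement
#'
#' Mixing-time correlations give \eqn{t_{95} \propto (P/\rho V)^{-1/3}}
#' and \eqn{t_{95} \propto V^{2/9}} at constant specific power, so a
#' rate_factor-fold faster mixing is equivalent to a
#' \code{rate_factor^3}-fold specific power input, or to operating a
#' \code{rate_factor^{9/2}}-fold smaller volume.
#'
#' @param rate_factor fold-change in mixing rate (> 0).
#' @return List with \code{rate_factor}, \code{power_factor}
#'   (= rate_factor^3) and \code{volume_factor} (= rate_factor^{9/2}).
#' @examples
#' scale_equivalents(2)$power_factor    # 8
#' scale_equivalents(10)$volume_factor  # ~31600
#' @export
scale_equivalents <- function(rate_factor) {
  if (!is.numeric(rate_factor) || any(rate_factor <= 0))
    stop("'rate_factor' must be positive")
  list(rate_factor = rate_factor,
       power_factor = rate_factor^3,
       volume_factor = rate_factor^(9 / 2))
}
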