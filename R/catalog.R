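#' Reactor specification
#'
#' Geometry and operating conditions of a stirred tank or bubble column.
#' Working height is \code{aspect_ratio * tank_diameter}; the working
#' volume must be consistent with the cylinder \eqn{\pi (T/2)^2 H} within
#' 2 percent.
#'
#' @param name identifier.
#' @param kind \code{"stirred_tank"} or \code{"bubble_column"}.
#' @param tank_diameter T (m).
#' @param working_volume V (m^3).
#' @param aspect_ratio H/T (dimensionless).
#' @param gas_holdup gas volume fraction in the dispersion (0 <= eps < 1).
#' @param superficial_gas_velocity uG (m/s) at half height.
#' @param n_impellers number of impellers (tanks).
#' @param impeller_ratio D/T (tanks).
#' @param stirrer_speed n (1/s) (tanks).
#' @param target_t95 optional top-feed mixing time (s) used as the
#'   calibration anchor for the absolute flow scale.
#' @return Object of class \code{"reactor_spec"}.
#' @export
reactor_spec <- function(name, kind = c("stirred_tank", "bubble_column"),
                         tank_diameter, working_volume, aspect_ratio,
                         gas_holdup = 0, superficial_gas_velocity = 0,
                         n_impellers = NA_integer_, impeller_ratio = NA_real_,
                         stirrer_speed = NA_real_, target_t95 = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(tank_diameter > 0, working_volume > 0, aspect_ratio > 0,
            gas_holdup >= 0, gas_holdup < 1)
  H <- aspect_ratio * tank_diameter
  vcyl <- pi * (tank_diameter / 2)^2 * H
  if (abs(vcyl - working_volume) / working_volume > 0.02)
    stop(sprintf("geometry inconsistent: pi(T/2)^2 H = %.3g vs V = %.3g",
                 vcyl, working_volume))
  if (kind == "stirred_tank" &&
      (is.na(n_impellers) || is.na(impeller_ratio) || is.na(stirrer_speed)))
    stop("stirred tanks need n_impellers, impeller_ratio and stirrer_speed")
  structure(list(name = name, kind = kind, tank_diameter = tank_diameter,
                 working_volume = working_volume, aspect_ratio = aspect_ratio,
                 height = H, gas_holdup = gas_holdup,
                 superficial_gas_velocity = superficial_gas_velocity,
                 n_impellers = as.integer(n_impellers),
                 impeller_ratio = impeller_ratio,
                 stirrer_speed = stirrer_speed,
                 target_t95 = target_t95),
            class = "reactor_spec")
}

#' @export
print.reactor_spec <- function(x, ...) {
  cat(sprintf("<reactor %s: %s, T = %.2f m, V = %.1f m^3, H/T = %.2f>\n",
              x$name, x$kind, x$tank_diameter, x$working_volume,
              x$aspect_ratio))
  invisible(x)
}

#' Catalog of the four modelled industrial reactors
#'
#' Two stirred tanks (R4: 23.8 m^3, four Rushton impellers; R1: 8.2 m^3,
#' single impeller) and two bubble columns (B13: 40.2 m^3, aspect ratio
#' 12.5; B6: 237 m^3, aspect ratio 5.95), with working volumes spanning
#' 8-237 m^3.  Each entry carries its literature top-feed mixing time as
#' the calibration anchor for the compartment network's flow scale.
#'
#' @param name optional single reactor name; omitting it returns the
#'   whole catalog as a named list.
#' @return A \code{reactor_spec} or list of them.
#' @examples
#' reactor_catalog("R4")
#' names(reactor_catalog())
#' @export
reactor_catalog <- function(name = NULL) {
  cat_ <- list(
    R4 = reactor_spec("R4", "stirred_tank", tank_diameter = 2.09,
                      working_volume = 23.8, aspect_ratio = 3.33,
                      gas_holdup = 0.059, superficial_gas_velocity = 0.00923,
                      n_impellers = 4, impeller_ratio = 1 / 3,
                      stirrer_speed = 115 / 60, target_t95 = 154),
    R1 = reactor_spec("R1", "stirred_tank", tank_diameter = 2.00,
                      working_volume = 8.17, aspect_ratio = 1.30,
                      gas_holdup = 0, superficial_gas_velocity = 0,
                      n_impellers = 1, impeller_ratio = 2 / 9,
                      stirrer_speed = 60 / 60, target_t95 = 141),
    B13 = reactor_spec("B13", "bubble_column", tank_diameter = 1.60,
                       working_volume = 40.2, aspect_ratio = 12.5,
                       gas_holdup = 0.233, superficial_gas_velocity = 0.25,
                       target_t95 = 103),
    B6 = reactor_spec("B6", "bubble_column", tank_diameter = 3.70,
                      working_volume = 237, aspect_ratio = 5.95,
                      gas_holdup = 0.17, superficial_gas_velocity = 0.065,
                      target_t95 = 135))
  if (is.null(name)) return(cat_)
  if (!name %in% names(cat_))
    stop("unknown reactor '", name, "'; catalog has: ",
         paste(names(cat_), collapse = ", "))
  cat_[[name]]
}

#' Kinetic and transfer parameters of the model organism
#'
#' Default parameter set for the fed-batch Monod bioreaction, oxygen
#' transfer, and population-balance simulations (glucose-limited
#' \emph{E. coli}-like culture at 35 C):
#' biomass X = 10 g/L, maximal specific uptake qS = 1 g/g/h, decay
#' qd = 0.025 1/h, substrate affinity KS = 0.025 g/L, oxygen affinity
#' KO = 0.1 mg/L, maximal yield YXS = 0.5 g/g, oxygen demand
#' YOS = 1.067 g/g, kLa = 180 1/h, oxygen solubility Oe = 12.69 mg/L,
#' growth adaptation time TX = 2.5 h, uptake adaptation time TS = 0.025 h,
#' class widths Dmu = YXS qS/10 = 0.05 1/h and Dq = qS/10 = 0.1 g/g/h,
#' carbonate pKa = 6.35, feed rate F = 4 g/L/h.
#'
#' @param ... named overrides of any default.
#' @return Object of class \code{"kinetic_params"} (a named list).
#' @examples
#' kinetic_params()$qS
#' kinetic_params(X = 50)$X
#' @export
kinetic_params <- function(...) {
  p <- list(X = 10, qS = 1, qd = 0.025, KS = 0.025, KO = 0.1,
            YXS = 0.5, YOS = 1.067, kLa = 180, Oe = 12.69,
            TX = 2.5, TS = 0.025, Dmu = 0.05, Dq = 0.10,
            pKa = 6.35, F = 4)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown kinetic parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all kinetic parameters must be strictly positive numbers")
  structure(p, class = "kinetic_params")
}
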