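#' Feed arrangement: parse an "AxRyTz" code or explicit points
#'
#' A feed arrangement \code{AxRyTz} places the radial-tangential pattern
#' RyTz at each of x optimal axial levels (\code{\link{optimal_axial_positions}}).
#' Supported patterns: \code{R1Tz} (z feed points on the 0.628 R optimum,
#' one per tangential subdivision) and \code{R2T2} (six points: the inner
#' 0.343 R ring one point per half-circle subdivision, the outer 0.787 R
#' ring two interleaved points per subdivision, weighted 0.302 : 0.698 by
#' the radial weight system).  Inner points sit at subdivision centres
#' and outer pairs at plus/minus a quarter subdivision.  \code{"Top"}
#' denotes the conventional single feed at the liquid surface on the
#' axis.
#'
#' Per-point weights multiply to: (1/x per axial level) x (radial weight
#' w_i) / (points on that ring), and always sum to 1.
#'
#' @param code arrangement code matching \code{Top|A<x>R<y>T<z>}, or
#'   \code{NULL} when giving explicit points.
#' @param points optional data frame with columns \code{z}, \code{r},
#'   \code{phi} (absolute coordinates, m and rad) and optionally
#'   \code{weight} (default equal).
#' @return Object of class \code{"feed_arrangement"} with a \code{points}
#'   data frame in fractional coordinates (\code{z_frac}, \code{r_frac},
#'   \code{phi}, \code{weight}) or absolute ones for explicit points.
#' @examples
#' feed_arrangement("A2R1T2")$points   # 4 points
#' feed_arrangement("A1R2T2")$points   # 6 points
#' @export
feed_arrangement <- function(code = NULL, points = NULL) {
  if (!is.null(points)) {
    stopifnot(is.data.frame(points), all(c("z", "r", "phi") %in% names(points)))
    if (is.null(points$weight)) points$weight <- 1 / nrow(points)
    points$weight <- points$weight / sum(points$weight)
    return(structure(list(code = if (is.null(code)) "explicit" else code,
                          points = points, absolute = TRUE),
                     class = "feed_arrangement"))
  }
  if (identical(code, "Top")) {
    pts <- data.frame(z_frac = 1, r_frac = 0, phi = 0, weight = 1)
    return(structure(list(code = "Top", points = pts, absolute = FALSE),
                     class = "feed_arrangement"))
  }
  m <- regmatches(code, regexec("^A([0-9]+)R([0-9]+)T([0-9]+)$", code))[[1]]
  if (length(m) != 4L)
    stop("feed code '", code, "' does not match the grammar ",
         "'Top' or 'A<x>R<y>T<z>' (x axial, y radial, z tangential ",
         "coordinates), e.g. Top, A1R1T1, A2R1T2, A4R2T2")
  x <- as.integer(m[2]); y <- as.integer(m[3]); z <- as.integer(m[4])
  if (x < 1 || y < 1 || z < 1) stop("feed counts must be positive")
  if (!(y == 1L || (y == 2L && z == 2L)))
    stop("unsupported radial-tangential pattern R", y, "T", z,
         ": the tangential point counts must follow the integer ratios of ",
         "the optimal radii; valid patterns are R1T1, R1T2 (any T with R1) ",
         "and R2T2")
  plan <- optimal_radial_placement(y)
  zf <- optimal_axial_positions(x)
  counts <- plan$tangential_counts       # points per subdivision, per ring
  sub_w <- 2 * pi / z                    # subdivision angle
  pts <- list()
  for (iz in seq_along(zf)) for (i in seq_len(y)) for (s in seq_len(z)) {
    centre <- (s - 0.5) * sub_w
    off <- if (counts[i] == 1L) 0 else
      ((seq_len(counts[i]) - (counts[i] + 1) / 2) / counts[i]) * sub_w / 2 * 2
    # counts points spread symmetrically about the centre, quarter-spacing
    phi <- (centre + off) %% (2 * pi)
    pts[[length(pts) + 1L]] <- data.frame(
      z_frac = zf[iz], r_frac = plan$radial_fractions[i], phi = phi,
      weight = (1 / x) * plan$weights[i] / (z * counts[i]))
  }
  pts <- do.call(rbind, pts)
  stopifnot(abs(sum(pts$weight) - 1) < 1e-10)
  structure(list(code = code, points = pts, absolute = FALSE,
                 n_axial = x, n_radial = y, n_tangential = z),
            class = "feed_arrangement")
}

#' @export
print.feed_arrangement <- function(x, ...) {
  cat("<feed arrangement ", x$code, ": ", nrow(x$points), " point(s)>\n",
      sep = "")
  invisible(x)
}

#' Map feed points to the nearest compartments
#'
#' Each feed point is assigned to the compartment with the nearest
#' centroid (Euclidean distance in Cartesian coordinates after
#' cylindrical conversion); weights of points landing in the same
#' compartment are summed.  \code{"Top"} maps directly to the topmost
#' axial layer at the innermost ring in the sector containing phi = 0.
#'
#' @param network a \code{\link{build_network}} result.
#' @param arrangement a \code{\link{feed_arrangement}}.
#' @return Data frame with columns \code{index} and \code{weight}
#'   (weights sum to 1).
#' @export
locate_feed_compartments <- function(network, arrangement) {
  stopifnot(inherits(arrangement, "feed_arrangement"))
  comp <- network$compartments
  H <- network$height; R <- network$radius
  nz <- network$grid[1]; nr <- network$grid[2]; nphi <- network$grid[3]
  if (identical(arrangement$code, "Top")) {
    i <- comp$index[comp$iz == nz & comp$ir == 1L & comp$iphi == 1L]
    return(data.frame(index = i, weight = 1))
  }
  p <- arrangement$points
  if (isTRUE(arrangement$absolute)) {
    zz <- p$z; rr <- p$r
  } else {
    zz <- p$z_frac * H; rr <- p$r_frac * R
  }
  if (any(zz < 0 | zz > H | rr < 0 | rr > R))
    stop("feed point outside the vessel (z in [0, H], r in [0, R])")
  px <- rr * cos(p$phi); py <- rr * sin(p$phi)
  cx <- comp$r * cos(comp$phi); cy <- comp$r * sin(comp$phi)
  scale2 <- (H^2 + R^2)
  pieces <- lapply(seq_len(nrow(p)), function(k) {
    d2 <- (cx - px[k])^2 + (cy - py[k])^2 + (comp$z - zz[k])^2
    # a feed point equidistant from several centroids (e.g. the centre
    # feed on a layer boundary) is split equally among them, preserving
    # the symmetry that cancels the antisymmetric modes
    tie <- which(d2 <= min(d2) + 1e-9 * scale2)
    data.frame(index = as.integer(comp$index[tie]),
               weight = p$weight[k] / length(tie))
  })
  pieces <- do.call(rbind, pieces)
  agg <- stats::aggregate(list(weight = pieces$weight),
                          list(index = pieces$index), sum)
  agg <- agg[order(agg$index), ]
  rownames(agg) <- NULL
  agg
}
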