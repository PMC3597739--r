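#' Depth curve relating the offset parameter alpha to relative depth
#'
#' The depth curve is the monotone mapping between the offset parameter
#' `alpha` (shift of a structure between the two detector images, in units
#' of the detector separation `deltaD`) and the relative depth `z/d0`. It
#' is built by forward-simulating a line scan over a unitary point
#' perturbation at each depth, localizing the perturbation extremum seen by
#' each detector with three-point parabolic sub-pixel refinement, and
#' recording `alpha = (x_minus - x_plus) / deltaD`.
#'
#' The curve depends on the background optical properties only through the
#' effective attenuation, and only weakly so over the soft-tissue range; it
#' is also insensitive to `d0` and to the specific detector arrangement as
#' long as the source axis projects between the two detectors.
#'
#' @param medium an [optical_medium()].
#' @param d0 slab thickness (mm).
#' @param deltaD detector separation (mm); the curve is built with the pair
#'   offset along x, without loss of generality.
#' @param z_step depth sampling step (mm), at most `d0/10`; default `d0/100`.
#' @param scan_step line-scan step (mm), at most `deltaD/20`;
#'   default `deltaD/40`.
#' @param arrangement `"symmetric"` or `"on_axis"` (see [pair_geometry()]).
#' @param inclusion optional extended [inclusion()] prototype (sphere or
#'   cube); its center is moved to each sampled depth. The default `NULL`
#'   uses the unitary point perturbation. The depth sweep for an extended
#'   inclusion is restricted so the inclusion stays inside the slab; the
#'   resulting curve is marked partial (it does not reach alpha 0 and 1).
#' @param quadrature_step lattice step for extended inclusions (mm).
#' @param cache reuse a per-session cached curve for identical parameters.
#' @return object of class `depth_curve` with a `samples` data frame
#'   (`alpha`, `z_over_d0`, strictly increasing) and build provenance.
#' @export
build_depth_curve <- function(medium, d0, deltaD,
                              z_step = d0 / 100, scan_step = deltaD / 40,
                              arrangement = c("symmetric", "on_axis"),
                              inclusion = NULL, quadrature_step = NULL,
                              cache = TRUE) {
  arrangement <- match.arg(arrangement)
  stopifnot(inherits(medium, "optical_medium"), d0 > 0, deltaD > 0)
  if (z_step <= 0 || z_step > d0 / 10) stop("need 0 < z_step <= d0/10")
  if (scan_step <= 0 || scan_step > deltaD / 20)
    stop("need 0 < scan_step <= deltaD/20")
  key <- paste(format(c(medium$mu_a0, medium$mu_s0_prime, d0, deltaD, z_step,
                        scan_step, quadrature_step), digits = 12),
               medium$convention, arrangement,
               if (is.null(inclusion)) "point" else
                 paste(inclusion$shape, format(inclusion$size)),
               collapse = "|")
  if (cache && !is.null(.dd_cache[[key]])) return(.dd_cache[[key]])

  geom <- pair_geometry(d0, c(deltaD, 0), arrangement)
  margin <- deltaD / 4 + 5
  xs <- seq(-(deltaD / 2 + margin), deltaD + margin, by = scan_step)
  zlim <- c(z_step, d0 - z_step)
  if (!is.null(inclusion)) {
    # keep the extended inclusion inside the slab; the curve is partial
    zlim <- c(max(zlim[1], inclusion$size / 2),
              min(zlim[2], d0 - inclusion$size / 2))
    if (zlim[2] <= zlim[1]) stop("inclusion too large for the slab")
  }
  zs <- seq(zlim[1], zlim[2], by = z_step)

  alpha <- vapply(zs, function(z) {
    if (is.null(inclusion)) {
      P <- matrix(c(0, 0, z), 1); w <- 1; rf <- 0
    } else {
      inc <- inclusion
      inc$center <- c(0, 0, z)
      q <- discretize_inclusion(inc, quadrature_step)
      P <- q$points; w <- q$weights
      rf <- (if (is.null(quadrature_step)) inc$size / 8 else quadrature_step) / 2
    }
    line_scan_alpha(medium, geom, xs, P, w, rf)
  }, numeric(1))

  samples <- data.frame(alpha = alpha, z_over_d0 = zs / d0)
  partial <- !is.null(inclusion)
  if (!partial)  # a defect on a scan plate has alpha exactly 0 or 1
    samples <- rbind(data.frame(alpha = 0, z_over_d0 = 0), samples,
                     data.frame(alpha = 1, z_over_d0 = 1))
  if (any(diff(samples$alpha) < -1e-4))
    stop("depth-curve localization failure: alpha not monotone in z")
  keep <- c(TRUE, diff(cummax(samples$alpha)) > 1e-9)
  samples <- samples[keep, ]
  curve <- structure(
    list(samples = samples, medium = medium, d0 = d0, deltaD = deltaD,
         arrangement = arrangement, partial = partial,
         provenance = list(z_step = z_step, scan_step = scan_step,
                           localization = "parabolic",
                           convention = medium$convention,
                           inclusion = if (is.null(inclusion)) "point" else
                             paste(inclusion$shape, inclusion$size, "mm"),
                           discrepancy_metric = "percent of d0 at matched alpha")),
    class = "depth_curve")
  if (cache) .dd_cache[[key]] <- curve
  curve
}

# alpha from one line scan over a fixed set of quadrature nodes
line_scan_alpha <- function(medium, geom, xs, P, w, r_floor) {
  S <- cbind(xs, 0, 0)
  prof <- function(offset) {
    D <- cbind(xs + offset[1], offset[2], geom$d0)
    born_kernel_sum(medium, S, D, P, w, r_floor = r_floor)
  }
  xp <- refine_minimum(xs, prof(geom$offset_plus))
  xm <- refine_minimum(xs, prof(geom$offset_minus))
  (xm - xp) / geom$deltaD
}

# three-point parabolic sub-pixel refinement of the profile minimum
refine_minimum <- function(xs, y) {
  i0 <- which.min(y)
  if (i0 == 1L || i0 == length(y))
    stop("extremum localization failed: minimum at scan edge")
  denom <- y[i0 - 1L] - 2 * y[i0] + y[i0 + 1L]
  delta <- if (denom > 0) 0.5 * (y[i0 - 1L] - y[i0 + 1L]) / denom else 0
  xs[i0] + max(-0.5, min(0.5, delta)) * (xs[2] - xs[1])
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf(
    "<depth_curve> d0 = %g mm, deltaD = %g mm, %s, %d samples%s (mu_eff = %.4g /mm)\n",
    x$d0, x$deltaD, x$arrangement, nrow(x$samples),
    if (x$partial) " [partial]" else "", x$medium$mu_eff))
  invisible(x)
}

#' @export
plot.depth_curve <- function(x, ...) {
  plot(x$samples$alpha, x$samples$z_over_d0, type = "l",
       xlab = expression(alpha), ylab = expression(z / d[0]),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

# monotone shape-preserving interpolant of the curve, either z/d0(alpha)
# (inverse = FALSE maps alpha -> z/d0) or alpha(z/d0)
curve_fun <- function(curve, inverse = FALSE) {
  s <- curve$samples
  if (inverse) splinefun(s$z_over_d0, s$alpha, method = "monoH.FC")
  else splinefun(s$alpha, s$z_over_d0, method = "monoH.FC")
}

#' Translate measured alpha values into depth
#'
#' Monotone piecewise-cubic interpolation of the depth curve, scaled by
#' `d0`. Values of `alpha` outside the curve's sampled range (possible for
#' partial extended-inclusion curves) are clamped to the range with a
#' warning; `NA` propagates.
#'
#' @param curve a [build_depth_curve()] result.
#' @param alpha offset parameter values in `[0, 1]` (NA allowed).
#' @return depths `z` in mm.
#' @export
invert_alpha <- function(curve, alpha) {
  stopifnot(inherits(curve, "depth_curve"))
  ok <- !is.na(alpha)
  if (any(alpha[ok] < 0 | alpha[ok] > 1)) stop("alpha must lie in [0, 1]")
  rng <- range(curve$samples$alpha)
  if (any(alpha[ok] < rng[1] | alpha[ok] > rng[2])) {
    if (curve$partial)
      warning("alpha outside the sampled range of a partial curve; clamped")
    alpha[ok] <- pmin(pmax(alpha[ok], rng[1]), rng[2])
  }
  z <- rep(NA_real_, length(alpha))
  z[ok] <- curve_fun(curve)(alpha[ok]) * curve$d0
  z
}

#' Expected alpha for a given depth
#'
#' Inverse companion of [invert_alpha()]: interpolates the curve to return
#' the offset parameter expected for a structure at depth `z`.
#'
#' @param curve a [build_depth_curve()] result.
#' @param z depth(s) in mm, within `[0, d0]`.
#' @return alpha values.
#' @export
depth_to_alpha <- function(curve, z) {
  stopifnot(inherits(curve, "depth_curve"))
  if (any(z < 0 | z > curve$d0, na.rm = TRUE)) stop("z must lie in [0, d0]")
  curve_fun(curve, inverse = TRUE)(z / curve$d0)
}

#' Depth interval from a one-pixel alpha uncertainty
#'
#' Propagates a measurement uncertainty of `pixel_pitch / deltaD` in alpha
#' through the depth curve, returning `invert_alpha` evaluated at
#' `alpha -/+ pitch/deltaD`, clipped to `[0, 1]`. Because the depth curve
#' is steep near both plates and shallow at mid-depth, the interval is
#' wider near the plates than at mid-depth.
#'
#' @param curve a [build_depth_curve()] result.
#' @param alpha measured offset parameter in `[0, 1]`.
#' @param pixel_pitch pixel size of the alpha measurement (mm).
#' @param deltaD detector separation of the measurement (mm); defaults to
#'   the curve's.
#' @return numeric `c(z_lo, z_hi)` in mm (a matrix for vector `alpha`).
#' @export
alpha_uncertainty_to_depth <- function(curve, alpha, pixel_pitch,
                                       deltaD = curve$deltaD) {
  stopifnot(pixel_pitch >= 0, deltaD > 0)
  da <- pixel_pitch / deltaD
  lo <- unname(invert_alpha(curve, pmax(0, alpha - da)))
  hi <- unname(invert_alpha(curve, pmin(1, alpha + da)))
  if (length(alpha) == 1L) c(z_lo = lo, z_hi = hi)
  else cbind(z_lo = lo, z_hi = hi)
}

#' Maximum discrepancy between two depth curves
#'
#' Maximum over a common alpha grid of the absolute difference in `z/d0`,
#' expressed in percent of `d0`. The comparison is restricted to the alpha
#' range sampled by both curves (relevant for partial curves).
#'
#' @param curve_a,curve_b [build_depth_curve()] results.
#' @param n number of alpha grid points.
#' @return percent of `d0` (a scalar).
#' @export
curve_discrepancy <- function(curve_a, curve_b, n = 201L) {
  stopifnot(inherits(curve_a, "depth_curve"), inherits(curve_b, "depth_curve"))
  lo <- max(min(curve_a$samples$alpha), min(curve_b$samples$alpha))
  hi <- min(max(curve_a$samples$alpha), max(curve_b$samples$alpha))
  if (hi <= lo) stop("curves share no alpha range")
  a <- seq(lo, hi, length.out = n)
  max(abs(curve_fun(curve_a)(a) - curve_fun(curve_b)(a))) * 100
}
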