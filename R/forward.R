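#' Raster scan image
#'
#' A 2D grid of transmitted intensity (or transmittance) indexed by source
#' scan position. Rows run along y, columns along x; the pixel `[1, 1]`
#' center sits at `origin` and pixel centers are spaced by `pitch` in both
#' directions. The two images of a detector pair share grid, pitch and
#' origin.
#'
#' @param values numeric matrix of strictly positive intensities.
#' @param pitch pixel pitch (mm), `> 0`.
#' @param origin length-2 `c(x, y)` of the first pixel center (mm).
#' @param detector detector label; canonically `"D_plus"`, `"D_minus"` or
#'   `"D_0"`, but any `"D_"`-prefixed label is accepted (multi-detector
#'   Monte Carlo runs label extra detectors `"D_1"`, `"D_2"`, ...).
#' @param geometry a [pair_geometry()].
#' @param medium an [optical_medium()] (optional for measured data).
#' @return object of class `scan_image`.
#' @export
scan_image <- function(values, pitch, origin, detector = "D_plus",
                       geometry = NULL, medium = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1L, ncol(values) >= 1L,
            pitch > 0, length(origin) == 2L,
            is.character(detector), startsWith(detector, "D_"))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("scan_image values must be finite and strictly positive")
  structure(
    list(values = values, pitch = pitch, origin = as.numeric(origin),
         detector = detector, geometry = geometry, medium = medium),
    class = "scan_image")
}

# pixel-center coordinate axes of a scan grid
scan_axes <- function(img) {
  list(x = img$origin[1] + (seq_len(ncol(img$values)) - 1L) * img$pitch,
       y = img$origin[2] + (seq_len(nrow(img$values)) - 1L) * img$pitch)
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %s, %d x %d px, pitch %g mm, origin (%g, %g) mm\n",
              x$detector, nrow(x$values), ncol(x$values), x$pitch,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
plot.scan_image <- function(x, main = x$detector, ...) {
  ax <- scan_axes(x)
  graphics::image(ax$x, ax$y, t(x$values), xlab = "x (mm)", ylab = "y (mm)",
                  main = main, asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(128), ...)
  invisible(x)
}

#' Infinite-medium CW diffusion Green's function
#'
#' Fluence per unit source power at distance `r` from an isotropic point
#' source in an infinite homogeneous diffusive medium:
#' `G(r) = exp(-mu_eff r) / (4 pi D r)`.
#'
#' @param medium an [optical_medium()].
#' @param r source-to-field distance(s), mm, `> 0`.
#' @return fluence values; strictly positive and strictly decreasing in `r`.
#' @examples
#' m <- optical_medium(per_cm(0.05), per_cm(5))
#' greens_function(m, c(10, 20, 40))
#' @export
greens_function <- function(medium, r) {
  stopifnot(inherits(medium, "optical_medium"))
  if (any(r <= 0)) stop("r must be > 0")
  exp(-medium$mu_eff * r) / (4 * pi * medium$D_coef * r)
}

# Born kernel summed over quadrature nodes, vectorized over scan rows.
# S, D: n x 3 source / detector positions; P: m x 3 nodes; w: m weights
# (delta_mu_a * dV, mm^2). Returns length-n relative perturbation dI/I0 =
# -sum_j w_j G(|s-p_j|) G(|p_j-d|) / G(|s-d|). r_floor regularizes the
# integrable 1/r singularity for quadrature nodes grazing the scan planes.
born_kernel_sum <- function(medium, S, D, P, w, r_floor = 0) {
  mu <- medium$mu_eff
  pref <- 1 / (4 * pi * medium$D_coef)
  r3 <- sqrt(rowSums((S - D)^2))
  if (any(r3 <= 0)) stop("source and detector positions must differ")
  acc <- numeric(nrow(S))
  for (j in seq_len(nrow(P))) {
    r1 <- sqrt((S[, 1] - P[j, 1])^2 + (S[, 2] - P[j, 2])^2 +
                 (S[, 3] - P[j, 3])^2)
    r2 <- sqrt((D[, 1] - P[j, 1])^2 + (D[, 2] - P[j, 2])^2 +
                 (D[, 3] - P[j, 3])^2)
    if (r_floor > 0) {
      r1 <- pmax(r1, r_floor)
      r2 <- pmax(r2, r_floor)
    } else if (any(r1 <= 0) || any(r2 <= 0)) {
      stop("perturbation position coincides with source or detector")
    }
    acc <- acc + w[j] * pref * r3 / (r1 * r2) * exp(-mu * (r1 + r2 - r3))
  }
  as.vector(-acc)
}

#' First-order Born relative perturbation of a point absorber
#'
#' Relative change in detected CW intensity, `dI/I0`, caused by a
#' point-like absorption perturbation of strength `V * delta_mu_a` at
#' `defect_pos`, for a source at `source_pos` and detector at `det_pos` in
#' an infinite medium:
#' `dI/I0 = -strength * G(|s-p|) G(|p-d|) / G(|s-d|)`.
#'
#' @param medium an [optical_medium()].
#' @param source_pos,det_pos,defect_pos length-3 positions (mm).
#' @param strength `V * delta_mu_a` (mm^2).
#' @return dimensionless relative perturbation (negative for an absorber).
#' @export
relative_perturbation_point <- function(medium, source_pos, det_pos,
                                        defect_pos, strength) {
  stopifnot(length(source_pos) == 3L, length(det_pos) == 3L,
            length(defect_pos) == 3L, is.numeric(strength))
  born_kernel_sum(medium, matrix(source_pos, 1), matrix(det_pos, 1),
                  matrix(defect_pos, 1), strength)
}

#' First-order Born relative perturbation of an extended inclusion
#'
#' Volume integral of the point Born kernel over an extended inclusion,
#' computed by the midpoint rule on a regular sub-voxel lattice (rods and
#' polylines are first discretized as chains of spheres of matching
#' diameter). Converges to [relative_perturbation_point()] as the inclusion
#' shrinks at fixed `V * delta_mu_a`.
#'
#' @inheritParams relative_perturbation_point
#' @param inclusion an [inclusion()] with finite volume.
#' @param quadrature_step midpoint lattice step (mm); at most half the
#'   smallest inclusion dimension. Default `size/8`.
#' @return dimensionless relative perturbation.
#' @export
relative_perturbation_extended <- function(medium, source_pos, det_pos,
                                           inclusion, quadrature_step = NULL) {
  q <- discretize_inclusion(inclusion, quadrature_step)
  h <- if (is.null(quadrature_step)) inclusion$size / 8 else quadrature_step
  born_kernel_sum(medium, matrix(source_pos, 1), matrix(det_pos, 1),
                  q$points, q$weights, r_floor = h / 2)
}

#' Simulate a paired detector scan with the diffusion forward model
#'
#' Scans the source over the grid of positions with the detector pair
#' rigidly attached, and evaluates the first-order Born perturbation of all
#' inclusions at every position. Returned intensities are
#' `I0 * (1 + dI/I0)` with `I0 = G(source-detector distance)`; with no
#' inclusions both images are spatially constant, and perturbations of
#' multiple inclusions add (first order).
#'
#' @param medium an [optical_medium()].
#' @param geometry a [pair_geometry()].
#' @param inclusions an [inclusion_set()] (may be empty).
#' @param grid list with numeric vectors `x` and `y`: scan positions (mm).
#' @param quadrature_step lattice step for extended inclusions (mm).
#' @param clip_z if `TRUE` (default), require every inclusion's z extent to
#'   lie within `[0, d0]`; curve building over an unbounded infinite medium
#'   may disable this.
#' @return list with elements `plus` and `minus`, both [scan_image()]s.
#' @export
simulate_scan <- function(medium, geometry, inclusions = inclusion_set(),
                          grid, quadrature_step = NULL, clip_z = TRUE) {
  stopifnot(inherits(medium, "optical_medium"),
            inherits(geometry, "pair_geometry"))
  if (!inherits(inclusions, "inclusion_set"))
    inclusions <- inclusion_set(inclusions)
  if (is.null(grid$x) || is.null(grid$y) ||
      length(grid$x) == 0L || length(grid$y) == 0L)
    stop("empty scan grid")
  if (length(grid$x) > 1L &&
      max(abs(diff(diff(grid$x)))) > 1e-9) stop("grid$x must be uniform")
  d0 <- geometry$d0
  if (clip_z) {
    for (inc in inclusions) {
      zr <- inclusion_z_range(inc)
      if (zr[1] < -1e-9 || zr[2] > d0 + 1e-9)
        stop("inclusion z extent must lie within [0, d0]")
    }
  }
  pos <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  n <- nrow(pos)
  S <- cbind(pos, 0)
  make_img <- function(offset, label) {
    D <- cbind(pos[, 1] + offset[1], pos[, 2] + offset[2], d0)
    I0 <- greens_function(medium, sqrt(sum(c(offset, d0)^2)))
    rel <- numeric(n)
    for (inc in inclusions) {
      q <- discretize_inclusion(inc, quadrature_step)
      h <- if (inc$shape == "point") 0 else
        if (is.null(quadrature_step)) inc$size / 8 else quadrature_step
      rel <- rel + born_kernel_sum(medium, S, D, q$points, q$weights,
                                   r_floor = h / 2)
    }
    vals <- I0 * (1 + rel)
    if (any(vals <= 0)) {
      warning("first-order perturbation exceeded -100%; intensities floored")
      vals <- pmax(vals, I0 * 1e-6)
    }
    scan_image(matrix(vals, nrow = length(grid$y), ncol = length(grid$x),
                      byrow = TRUE),
               pitch = if (length(grid$x) > 1L) diff(grid$x[1:2]) else 1,
               origin = c(grid$x[1], grid$y[1]), detector = label,
               geometry = geometry, medium = medium)
  }
  list(plus = make_img(geometry$offset_plus, "D_plus"),
       minus = make_img(geometry$offset_minus, "D_minus"))
}

#' Multiplicative Gaussian measurement noise
#'
#' Applies `I * (1 + sigma_frac * eps)` with `eps ~ N(0, 1)` i.i.d. per
#' pixel, flooring at a small positive value. Used by the synthetic scene
#' pipeline; `sigma_frac = 0` returns the image unchanged.
#'
#' @param image a [scan_image()].
#' @param sigma_frac fractional noise standard deviation.
#' @param seed integer seed for reproducibility.
#' @return a [scan_image()].
#' @export
add_scan_noise <- function(image, sigma_frac, seed = 1L) {
  stopifnot(inherits(image, "scan_image"), sigma_frac >= 0)
  if (sigma_frac == 0) return(image)
  v <- image$values
  eps <- withr_rnorm(length(v), seed)
  v <- v * (1 + sigma_frac * eps)
  v <- pmax(v, min(image$values) * 1e-3)
  image$values <- matrix(v, nrow(image$values))
  image
}

# local-seed normal draws that do not disturb the global RNG stream
withr_rnorm <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}
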