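#' Convert per-centimeter optical coefficients to per-millimeter
#'
#' All internal computations use millimeters and 1/mm. Published optical
#' properties are usually quoted in 1/cm; this helper converts them.
#'
#' @param x coefficient in 1/cm.
#' @return coefficient in 1/mm.
#' @examples
#' per_cm(0.05)  # 0.005 / mm
#' @export
per_cm <- function(x) x / 10

#' Homogeneous background optical medium
#'
#' Describes the diffusive background (e.g. compressed breast tissue or a
#' milk phantom) by its absorption and reduced scattering coefficients, and
#' derives the diffusion coefficient and effective attenuation used by the
#' continuous-wave Green's function.
#'
#' Two diffusion-coefficient conventions are in common use. The default,
#' `"mua_independent"`, takes `D = 1/(3 mu_s')` and
#' `mu_eff = sqrt(3 mu_a mu_s')`; the alternative `"mua_inclusive"` takes
#' `D = 1/(3 (mu_a + mu_s'))` and `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`.
#' For the weakly absorbing media targeted here the two differ by well
#' under a percent; the convention in force is recorded in the object and
#' propagated to every output.
#'
#' @param mu_a0 background absorption coefficient (1/mm), `>= 0`.
#' @param mu_s0_prime background reduced scattering coefficient (1/mm), `> 0`.
#' @param convention diffusion-coefficient convention (see Details).
#' @return an object of class `optical_medium` with fields `mu_a0`,
#'   `mu_s0_prime`, `D_coef` (mm) and `mu_eff` (1/mm).
#' @examples
#' optical_medium(per_cm(0.05), per_cm(5))
#' @export
optical_medium <- function(mu_a0, mu_s0_prime,
                           convention = c("mua_independent", "mua_inclusive")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(mu_a0), length(mu_a0) == 1L, mu_a0 >= 0,
            is.numeric(mu_s0_prime), length(mu_s0_prime) == 1L,
            mu_s0_prime > 0)
  mu_t <- if (convention == "mua_inclusive") mu_a0 + mu_s0_prime else mu_s0_prime
  structure(
    list(mu_a0 = mu_a0, mu_s0_prime = mu_s0_prime,
         D_coef = 1 / (3 * mu_t),
         mu_eff = sqrt(3 * mu_a0 * mu_t),
         convention = convention),
    class = "optical_medium")
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf(
    "<optical_medium> mu_a0 = %g /mm, mu_s0' = %g /mm (D = %.4g mm, mu_eff = %.4g /mm, %s)\n",
    x$mu_a0, x$mu_s0_prime, x$D_coef, x$mu_eff, x$convention))
  invisible(x)
}

#' Detector-pair scanning geometry
#'
#' A source fiber on the `z = 0` plate and two detector fibers on the
#' `z = d0` plate are scanned in tandem over the x-y plane. The two
#' detectors of a pair are separated by the in-plane vector `deltaD_vec`
#' (from the "minus" to the "plus" detector). In the `"symmetric"`
#' arrangement the detectors sit at `+deltaD/2` and `-deltaD/2` about the
#' source axis; in the `"on_axis"` arrangement one detector is on-axis
#' (the "plus"/reference detector, labelled D0) and the other is offset by
#' `-deltaD_vec`. In both cases the source-axis projection lies on the
#' segment joining the two detectors, as required for the offset parameter
#' alpha to span [0, 1].
#'
#' @param d0 source-plate-to-detector-plate separation (mm), `> 0`.
#' @param deltaD_vec length-2 in-plane offset vector between the detectors
#'   of the pair (mm); its norm is `deltaD`.
#' @param arrangement `"symmetric"` or `"on_axis"`.
#' @return object of class `pair_geometry` with detector offsets
#'   `offset_plus`, `offset_minus` (mm, relative to the source axis),
#'   `deltaD` and the unit vector `deltaD_hat`.
#' @examples
#' pair_geometry(40, c(20, 0))
#' @export
pair_geometry <- function(d0, deltaD_vec, arrangement = c("symmetric", "on_axis")) {
  arrangement <- match.arg(arrangement)
  stopifnot(is.numeric(d0), length(d0) == 1L, d0 > 0,
            is.numeric(deltaD_vec), length(deltaD_vec) == 2L)
  dD <- sqrt(sum(deltaD_vec^2))
  if (dD <= 0) stop("|deltaD_vec| must be > 0")
  if (arrangement == "symmetric") {
    op <- deltaD_vec / 2
    om <- -deltaD_vec / 2
  } else {
    op <- c(0, 0)
    om <- -deltaD_vec
  }
  structure(
    list(d0 = d0, deltaD_vec = as.numeric(deltaD_vec), deltaD = dD,
         deltaD_hat = deltaD_vec / dD, arrangement = arrangement,
         offset_plus = op, offset_minus = om),
    class = "pair_geometry")
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf("<pair_geometry> d0 = %g mm, deltaD = (%g, %g) mm, %s\n",
              x$d0, x$deltaD_vec[1], x$deltaD_vec[2], x$arrangement))
  invisible(x)
}

#' Absorbing inclusions
#'
#' Constructors for the inclusion shapes supported by the forward models:
#' a point perturbation of given strength `V * delta_mu_a` (mm^2), a
#' sphere, a cube, a finite cylinder (rod) between two axis endpoints, and
#' a polyline "vessel" along a vertex list. Rods and polylines are
#' discretized for the volume integrals as chains of spheres whose diameter
#' matches the rod diameter.
#'
#' @param center,p1,p2 coordinates in mm, `c(x, y, z)` with z measured from
#'   the source plate toward the detector plate.
#' @param strength `V * delta_mu_a` of a point perturbation (mm^2), `> 0`.
#' @param size diameter (sphere, cylinder, polyline) or edge length (cube),
#'   mm.
#' @param delta_mu_a absorption contrast over the background (1/mm), `> 0`.
#' @param vertices numeric matrix with columns x, y, z (mm).
#' @return object of class `inclusion`.
#' @name inclusion
NULL

new_inclusion <- function(shape, fields) {
  structure(c(list(shape = shape), fields), class = "inclusion")
}

#' @rdname inclusion
#' @export
inclusion_point <- function(center, strength) {
  stopifnot(length(center) == 3L, is.numeric(strength), strength > 0)
  new_inclusion("point", list(center = as.numeric(center), strength = strength))
}

#' @rdname inclusion
#' @export
inclusion_sphere <- function(center, size, delta_mu_a) {
  stopifnot(length(center) == 3L, size > 0, delta_mu_a > 0)
  new_inclusion("sphere", list(center = as.numeric(center), size = size,
                               delta_mu_a = delta_mu_a))
}

#' @rdname inclusion
#' @export
inclusion_cube <- function(center, size, delta_mu_a) {
  stopifnot(length(center) == 3L, size > 0, delta_mu_a > 0)
  new_inclusion("cube", list(center = as.numeric(center), size = size,
                             delta_mu_a = delta_mu_a))
}

#' @rdname inclusion
#' @export
inclusion_cylinder <- function(p1, p2, size, delta_mu_a) {
  stopifnot(length(p1) == 3L, length(p2) == 3L, size > 0, delta_mu_a > 0)
  if (sum((p1 - p2)^2) == 0) stop("cylinder endpoints must differ")
  new_inclusion("cylinder", list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                                 size = size, delta_mu_a = delta_mu_a))
}

#' @rdname inclusion
#' @export
inclusion_polyline <- function(vertices, size, delta_mu_a) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3L, nrow(vertices) >= 2L, size > 0, delta_mu_a > 0)
  new_inclusion("polyline", list(vertices = vertices, size = size,
                                 delta_mu_a = delta_mu_a))
}

#' @export
print.inclusion <- function(x, ...) {
  cat(sprintf("<inclusion> %s\n", x$shape))
  invisible(x)
}

#' Collect inclusions into a set
#'
#' @param ... `inclusion` objects (or a single list of them).
#' @return object of class `inclusion_set` (a list of inclusions).
#' @export
inclusion_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "inclusion"))
    xs <- xs[[1]]
  if (!all(vapply(xs, inherits, logical(1), "inclusion")))
    stop("all elements must be inclusion objects")
  structure(xs, class = "inclusion_set")
}

# z range spanned by an inclusion (for slab validation)
inclusion_z_range <- function(inc) {
  switch(inc$shape,
    point = rep(inc$center[3], 2),
    sphere = inc$center[3] + c(-1, 1) * inc$size / 2,
    cube = inc$center[3] + c(-1, 1) * inc$size / 2,
    cylinder = range(c(inc$p1[3], inc$p2[3])) + c(-1, 1) * inc$size / 2,
    polyline = range(inc$vertices[, 3]) + c(-1, 1) * inc$size / 2)
}

# resolve centers of the sphere chain for rods / polylines
chain_centers <- function(pts, size, spacing = size) {
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / spacing))
    tt <- seq(0, 1, length.out = n + 1L)
    if (i > 1L) tt <- tt[-1L]  # avoid duplicating shared vertices
    out[[i]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

# sphere chain representation (centers + radius + delta_mu_a) of an inclusion;
# NULL for shapes that are not chains of spheres
as_sphere_chain <- function(inc) {
  switch(inc$shape,
    sphere = list(centers = matrix(inc$center, 1), radius = inc$size / 2,
                  delta_mu_a = inc$delta_mu_a),
    cylinder = list(centers = chain_centers(rbind(inc$p1, inc$p2), inc$size),
                    radius = inc$size / 2, delta_mu_a = inc$delta_mu_a),
    polyline = list(centers = chain_centers(inc$vertices, inc$size),
                    radius = inc$size / 2, delta_mu_a = inc$delta_mu_a),
    NULL)
}

#' Discretize an inclusion for volume quadrature
#'
#' Returns midpoint-rule quadrature nodes and weights for the Born volume
#' integral: a matrix of voxel centers and a vector of weights
#' `delta_mu_a * h^3` (mm^2 each). Point inclusions return their center
#' with weight `strength`. Rods and polylines are first replaced by chains
#' of spheres of matching diameter, each sphere then voxelized.
#'
#' @param inc an `inclusion`.
#' @param quadrature_step midpoint-lattice step `h` (mm). Must be at most
#'   half the smallest inclusion dimension; defaults to 1/8 of the size.
#' @return list with `points` (n x 3 matrix, mm) and `weights` (mm^2).
#' @export
discretize_inclusion <- function(inc, quadrature_step = NULL) {
  stopifnot(inherits(inc, "inclusion"))
  if (inc$shape == "point")
    return(list(points = matrix(inc$center, 1), weights = inc$strength))
  if (is.null(quadrature_step)) quadrature_step <- inc$size / 8
  if (quadrature_step > inc$size / 2)
    stop(sprintf(paste0(
      "quadrature_step (%g mm) too coarse for inclusion size %g mm; ",
      "use a step of at most half the smallest dimension"),
      quadrature_step, inc$size))
  h <- quadrature_step
  lattice <- function(center, half) {
    n <- max(1L, ceiling(2 * half / h))
    ax <- function(c0) c0 + ((seq_len(n) - (n + 1) / 2) * h)
    as.matrix(expand.grid(x = ax(center[1]), y = ax(center[2]),
                          z = ax(center[3])))
  }
  if (inc$shape == "cube") {
    pts <- lattice(inc$center, inc$size / 2)
    keep <- apply(abs(sweep(pts, 2, inc$center)) <= inc$size / 2 + 1e-9, 1, all)
    pts <- pts[keep, , drop = FALSE]
    w <- inc$delta_mu_a * inc$size^3 / nrow(pts)   # exact cube volume
    return(list(points = unname(pts), weights = rep(w, nrow(pts))))
  }
  # rods/polylines: chain of spheres of matching diameter. For the smooth
  # Born quadrature the spheres overlap at half-diameter spacing (weights
  # scaled to preserve volume per unit length), which avoids imprinting a
  # periodic lumpiness on the synthesized images.
  ch <- switch(inc$shape,
    sphere = as_sphere_chain(inc),
    list(centers = chain_centers(
           if (inc$shape == "cylinder") rbind(inc$p1, inc$p2) else inc$vertices,
           inc$size, spacing = inc$size / 2),
         radius = inc$size / 2, delta_mu_a = inc$delta_mu_a))
  wscale <- if (inc$shape == "sphere") 1 else 0.5
  # normalize each sphere's voxel weights to its analytic volume: the
  # staircase boundary of the midpoint lattice otherwise dominates the
  # quadrature error (first order in h)
  vol <- 4 / 3 * pi * ch$radius^3
  pts <- list(); wts <- list()
  for (i in seq_len(nrow(ch$centers))) {
    p <- lattice(ch$centers[i, ], ch$radius)
    d2 <- rowSums(sweep(p, 2, ch$centers[i, ])^2)
    p <- p[d2 <= ch$radius^2 + 1e-9, , drop = FALSE]
    pts[[i]] <- p
    wts[[i]] <- rep(ch$delta_mu_a * wscale * vol / nrow(p), nrow(p))
  }
  pts <- do.call(rbind, pts)
  if (nrow(pts) == 0L) stop("quadrature produced no interior nodes")
  list(points = unname(pts), weights = unlist(wts))
}
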