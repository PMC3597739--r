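#' Monte Carlo scan configuration
#'
#' Configuration for the photon random-walk transport model: a laterally
#' infinite slab of thickness `d0` with absorbing spherical inclusions
#' (rods and polylines are expanded into chains of spheres of matching
#' diameter), a raster of source scan positions, and a set of detector
#' discs on the exit plane at fixed in-plane offsets from the source axis.
#' Transport runs in the reduced (isotropic-scattering) picture with
#' continuous absorption weighting; boundaries are index-matched and
#' photons are terminated on crossing either plate.
#'
#' @param medium an [optical_medium()].
#' @param d0 slab thickness (mm).
#' @param inclusions an [inclusion_set()] of spheres, cylinders or
#'   polylines, fully inside the slab.
#' @param scan_x,scan_y scan position coordinates (mm); the scan raster is
#'   their outer grid (use a single `scan_y` value for a line scan).
#' @param det_offsets 2-column matrix of detector offsets from the source
#'   axis (mm), one row per detector; or a [pair_geometry()] whose
#'   plus/minus offsets are used.
#' @param det_radius detector disc radius (mm), `> 0`.
#' @param photons number of launched photons, `>= 1`.
#' @param seed integer seed; a fixed seed reproduces the output bitwise.
#' @param roulette_thresh,roulette_p Russian-roulette weight threshold and
#'   survival probability.
#' @param boundaries `"slab"` (photons terminated on crossing either
#'   plate, index-matched) or `"open"` (effectively infinite medium:
#'   photons may wander below the source plane and return; detection at
#'   the first crossing of the exit plane). The open mode matches the
#'   infinite-medium framing of the depth curve and of deeply immersed
#'   liquid-phantom experiments.
#' @param source `"pencil"` (collimated beam entering along +z) or
#'   `"isotropic"` (isotropic point emission at the source position, the
#'   transport analog of the diffusion point source used by the depth
#'   curve; natural with open boundaries).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(medium, d0, inclusions = inclusion_set(),
                      scan_x, scan_y = 0, det_offsets, det_radius = 3,
                      photons = 1e6, seed = 1L,
                      roulette_thresh = 1e-4, roulette_p = 0.1,
                      boundaries = c("slab", "open"),
                      source = c("pencil", "isotropic")) {
  boundaries <- match.arg(boundaries)
  source <- match.arg(source)
  stopifnot(inherits(medium, "optical_medium"), d0 > 0, det_radius > 0,
            photons >= 1, length(scan_x) >= 1L, length(scan_y) >= 1L)
  if (!inherits(inclusions, "inclusion_set"))
    inclusions <- inclusion_set(inclusions)
  geometry <- NULL
  if (inherits(det_offsets, "pair_geometry")) {
    geometry <- det_offsets
    if (geometry$d0 != d0) stop("pair_geometry d0 disagrees with slab d0")
    det_offsets <- rbind(geometry$offset_plus, geometry$offset_minus)
  }
  det_offsets <- as.matrix(det_offsets)
  stopifnot(ncol(det_offsets) == 2L)
  spheres <- list()
  for (inc in inclusions) {
    zr <- inclusion_z_range(inc)
    if (zr[1] < -1e-9 || zr[2] > d0 + 1e-9)
      stop("MC inclusions must lie inside the slab")
    ch <- as_sphere_chain(inc)
    if (is.null(ch))
      stop("MC transport supports sphere, cylinder and polyline inclusions")
    spheres[[length(spheres) + 1L]] <-
      cbind(ch$centers, ch$radius, ch$delta_mu_a)
  }
  spheres <- if (length(spheres)) do.call(rbind, spheres) else
    matrix(numeric(0), 0, 5)
  structure(
    list(medium = medium, d0 = d0, inclusions = inclusions,
         spheres = spheres, scan_x = as.numeric(scan_x),
         scan_y = as.numeric(scan_y), det_offsets = det_offsets,
         geometry = geometry, det_radius = det_radius,
         photons = as.integer(photons), seed = as.integer(seed),
         roulette_thresh = roulette_thresh, roulette_p = roulette_p,
         boundaries = boundaries, source = source),
    class = "mc_config")
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf(
    "<mc_config> d0 = %g mm, %d detector(s), %d x %d scan, %d sphere(s), %g photons, seed %d\n",
    x$d0, nrow(x$det_offsets), length(x$scan_x), length(x$scan_y),
    nrow(x$spheres), x$photons, x$seed))
  invisible(x)
}

#' Run a Monte Carlo detector scan
#'
#' Simulates the transmittance raster for every detector offset. Transport
#' is run once from a fixed source (the homogeneous slab is translation
#' invariant, so scanning the source is equivalent to translating the
#' inclusions); the stored paths of detected photons are then re-scored at
#' every scan position through exact ray-sphere path lengths, giving
#' correlated sampling across scan positions.
#'
#' @param config an [mc_config()].
#' @param n_batch number of batches for the per-pixel standard error.
#' @param return_paths also return the stored detector-1 photon paths (for
#'   independent re-scoring in validation work).
#' @return list with `images` (one [scan_image()] of detected photon-weight
#'   transmittance per detector), `se` (matching standard-error matrices),
#'   `T_hom` (homogeneous-slab transmittance per detector), `n_detected`,
#'   and `bookkeeping` (weight conservation terms).
#' @export
run_mc_scan <- function(config, n_batch = 16L, return_paths = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  sx <- config$scan_x; sy <- config$scan_y
  if (length(sx) > 1L && max(abs(diff(diff(sx)))) > 1e-9)
    stop("scan_x must be a regular grid")
  if (length(sy) > 1L && max(abs(diff(diff(sy)))) > 1e-9)
    stop("scan_y must be a regular grid")
  res <- mc_scan_cpp(config$photons, config$medium$mu_s0_prime,
                     config$medium$mu_a0, config$d0,
                     config$det_offsets, config$det_radius,
                     sx[1], if (length(sx) > 1L) sx[2] - sx[1] else 1,
                     length(sx),
                     sy[1], if (length(sy) > 1L) sy[2] - sy[1] else 1,
                     length(sy),
                     config$spheres, config$seed,
                     config$roulette_thresh, config$roulette_p,
                     as.integer(n_batch), 200000L,
                     identical(config$boundaries, "open"),
                     identical(config$source, "isotropic"), return_paths)
  ny <- length(config$scan_y); nx <- length(config$scan_x)
  pitch <- if (nx > 1L) diff(config$scan_x[1:2]) else
    if (ny > 1L) diff(config$scan_y[1:2]) else 1
  labels <- if (nrow(config$det_offsets) == 2L && !is.null(config$geometry))
    c("D_plus", "D_minus") else paste0("D_", seq_len(nrow(config$det_offsets)))
  images <- vector("list", nrow(config$det_offsets))
  se <- vector("list", nrow(config$det_offsets))
  for (k in seq_len(nrow(config$det_offsets))) {
    vals <- res$T[, k]
    if (all(vals <= 0))
      stop("no photons detected for detector ", k, "; increase the budget")
    if (any(vals <= 0)) {
      warning("pixels with zero detected weight for detector ", k,
              "; floored")
      vals[vals <= 0] <- min(vals[vals > 0]) * 1e-3
    }
    images[[k]] <- scan_image(matrix(vals, nrow = ny, ncol = nx, byrow = TRUE),
                              pitch = pitch,
                              origin = c(config$scan_x[1], config$scan_y[1]),
                              detector = labels[k],
                              geometry = config$geometry,
                              medium = config$medium)
    se[[k]] <- matrix(res$SE[, k], nrow = ny, ncol = nx, byrow = TRUE)
  }
  names(images) <- names(se) <- labels
  list(images = images, se = se, T_hom = as.numeric(res$T_hom),
       n_detected = as.integer(res$n_detected),
       bookkeeping = res$bookkeeping,
       paths = if (return_paths) res$paths else NULL)
}

#' Weight-conservation residual of an MC run
#'
#' Checks the bookkeeping identity `launched + roulette boost = absorbed +
#' escaped + transmitted + roulette killed + lost`, returned as a fraction
#' of the launched weight.
#'
#' @param run a [run_mc_scan()] result.
#' @return relative residual (should be at numerical precision).
#' @export
mc_energy_residual <- function(run) {
  b <- run$bookkeeping
  abs(b$launched + b$roulette_boost -
        (b$absorbed + b$escaped + b$transmitted + b$roulette_killed +
           b$lost)) / b$launched
}

# 2D point-to-segment distance
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

#' Monte Carlo depth-recovery experiment
#'
#' Runs [run_mc_scan()] for a two-detector pair configuration and feeds the
#' images through the full pipeline (optional interpolation, curvature,
#' skeletonization, inner-product matching, depth inversion), then
#' summarizes the recovered depth per inclusion. Matched pixels live in the
#' `D_plus` image frame, where a structure at depth z appears displaced by
#' `-offset_plus * z/d0` from its true lateral position; each pixel is
#' mapped back to object coordinates with its own recovered depth before
#' being assigned to the inclusion whose x-y projection (point, or segment
#' for rods) is nearest. Pixels whose two nearest projections are closer
#' than `exclude_radius` apart (e.g. at a rod crossing) are excluded from
#' the per-object summary but retained in the returned depth map. Besides
#' the mean/median over assigned pixels, the summary reports `valley_z`,
#' the depth at the assigned pixel with the deepest curvature (the valley
#' reading used for isolated inclusions).
#'
#' @param config an [mc_config()] built with a [pair_geometry()].
#' @param curve a [build_depth_curve()] for the inversion.
#' @param objects list of object descriptors: each a list with `name` and
#'   either `point = c(x, y)` or `segment = list(p1, p2)` (mm, projections).
#' @param window matching window edge (mm).
#' @param smooth_fwhm optional Gaussian pre-smoothing FWHM (mm) applied to
#'   the stochastic images before enhancement (see [smooth_scan()]);
#'   `NULL` disables.
#' @param target_pitch optional interpolation pitch (mm); `NULL` keeps the
#'   scan pitch.
#' @param noise_floor skeleton threshold; `NULL` for the MAD default.
#' @param exclude_radius ambiguity exclusion distance (mm).
#' @param assign_radius maximum projection distance for assignment (mm).
#' @param n_batch batches for standard errors.
#' @return list with `summary` (data frame: object, n, mean_z, sd_z,
#'   median_z), `depth` (matrix, mm), `amap`, `skeletons`, `images`, `run`.
#' @export
mc_depth_experiment <- function(config, curve, objects, window = 4,
                                smooth_fwhm = NULL, target_pitch = NULL,
                                noise_floor = NULL,
                                exclude_radius = 4, assign_radius = 6,
                                n_batch = 16L) {
  stopifnot(inherits(config, "mc_config"), !is.null(config$geometry))
  run <- run_mc_scan(config, n_batch = n_batch)
  imgs <- run$images[c("D_plus", "D_minus")]
  if (!is.null(smooth_fwhm))
    imgs <- lapply(imgs, smooth_scan, fwhm = smooth_fwhm)
  if (!is.null(target_pitch))
    imgs <- lapply(imgs, interpolate_grid, target_pitch = target_pitch)
  curv <- lapply(imgs, second_derivative_image)
  skels <- lapply(curv, skeletonize, noise_floor = noise_floor)
  dvec <- config$geometry$deltaD_vec
  amap <- alpha_map(skels$D_plus, skels$D_minus, dvec, window = window)
  depth <- pair_depth(amap, curve)

  pitch <- imgs$D_plus$pitch
  origin <- imgs$D_plus$origin
  idx <- which(!is.na(depth), arr.ind = TRUE)
  rows <- list()
  if (nrow(idx) > 0) {
    # map D_plus-frame pixels to object coordinates with their own depth
    op <- config$geometry$offset_plus
    zrel <- depth[idx] / config$d0
    xy <- cbind(origin[1] + (idx[, 2] - 1L) * pitch + op[1] * zrel,
                origin[2] + (idx[, 1] - 1L) * pitch + op[2] * zrel)
    dmat <- sapply(objects, function(ob) {
      if (!is.null(ob$point))
        sqrt((xy[, 1] - ob$point[1])^2 + (xy[, 2] - ob$point[2])^2)
      else
        apply(xy, 1, dist_to_segment, a = ob$segment[[1]][1:2],
              b = ob$segment[[2]][1:2])
    })
    dmat <- matrix(dmat, nrow = nrow(idx))
    nearest <- apply(dmat, 1, which.min)
    dsort <- t(apply(dmat, 1, sort))
    ambiguous <- if (length(objects) > 1L)
      (dsort[, 2] - dsort[, 1]) < exclude_radius else rep(FALSE, nrow(idx))
    curv_vals <- curv$D_plus$values
    for (k in seq_along(objects)) {
      sel <- nearest == k & !ambiguous & dmat[cbind(seq_len(nrow(idx)), k)] <=
        assign_radius
      zk <- depth[idx[sel, , drop = FALSE]]
      ck <- curv_vals[idx[sel, , drop = FALSE]]
      rows[[k]] <- data.frame(
        object = objects[[k]]$name, n = length(zk),
        mean_z = if (length(zk)) mean(zk) else NA_real_,
        sd_z = if (length(zk) > 1L) sd(zk) else NA_real_,
        median_z = if (length(zk)) median(zk) else NA_real_,
        valley_z = if (length(zk)) zk[which.min(ck)] else NA_real_)
    }
  } else {
    rows <- lapply(objects, function(ob)
      data.frame(object = ob$name, n = 0L, mean_z = NA_real_,
                 sd_z = NA_real_, median_z = NA_real_, valley_z = NA_real_))
  }
  list(summary = do.call(rbind, rows), depth = depth, amap = amap,
       skeletons = skels, images = imgs, run = run)
}

#' Depth at the scan location nearest a given x-y point
#'
#' Convenience accessor for querying a depth matrix (e.g. at the crossing
#' point of two rods): returns the depth of the matched pixel nearest to
#' `xy`, or NA if none lies within `radius`.
#'
#' @param depth depth matrix from [mc_depth_experiment()] or [pair_depth()].
#' @param xy length-2 query point (mm).
#' @param pitch,origin grid metadata of the depth matrix.
#' @param radius search radius (mm).
#' @return depth in mm, or NA.
#' @export
depth_at <- function(depth, xy, pitch, origin, radius = 3) {
  idx <- which(!is.na(depth), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  px <- origin[1] + (idx[, 2] - 1L) * pitch
  py <- origin[2] + (idx[, 1] - 1L) * pitch
  d2 <- (px - xy[1])^2 + (py - xy[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > radius) return(NA_real_)
  depth[idx[i, 1], idx[i, 2]]
}
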