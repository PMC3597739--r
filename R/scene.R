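#' Synthetic scene specification
#'
#' A scene bundles everything needed to synthesize a paired-detector
#' experiment: the background medium, slab thickness, one or more detector
#' pairs, the scan grid, the inclusions, a multiplicative noise level, the
#' forward method (`"diffusion"` Born model or `"mc"` photon transport) and
#' a seed. Scenes round-trip losslessly through YAML
#' ([write_scene()] / [read_scene()]).
#'
#' @param name scene name.
#' @param medium an [optical_medium()] for the synthesis.
#' @param d0 slab thickness (mm).
#' @param pairs list of length-2 detector offset vectors (mm), one per pair.
#' @param grid list with `x = c(from, to)`, `y = c(from, to)`, `pitch`.
#' @param inclusions an [inclusion_set()].
#' @param arrangement detector arrangement (see [pair_geometry()]).
#' @param noise_sigma multiplicative Gaussian noise fraction (default 0).
#' @param seed integer seed for noise / MC.
#' @param method `"diffusion"` or `"mc"`.
#' @param curve_medium [optical_medium()] for the depth-curve lookup
#'   (defaults to `medium`); kept separate because analysis may use a
#'   standard curve rather than the exact phantom properties.
#' @param mc list of MC settings (`photons`, `det_radius`, `boundaries`,
#'   `source`; see [mc_config()]).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(name, medium, d0, pairs, grid, inclusions,
                       arrangement = "symmetric", noise_sigma = 0,
                       seed = 1L, method = c("diffusion", "mc"),
                       curve_medium = medium,
                       mc = list(photons = 4e6, det_radius = 3,
                                 boundaries = "slab", source = "pencil")) {
  mc <- modifyList(list(photons = 4e6, det_radius = 3,
                        boundaries = "slab", source = "pencil"), mc)
  method <- match.arg(method)
  stopifnot(inherits(medium, "optical_medium"), d0 > 0,
            length(pairs) >= 1L, noise_sigma >= 0)
  if (!inherits(inclusions, "inclusion_set"))
    inclusions <- inclusion_set(inclusions)
  structure(
    list(name = name, medium = medium, d0 = d0, pairs = pairs, grid = grid,
         inclusions = inclusions, arrangement = arrangement,
         noise_sigma = noise_sigma, seed = as.integer(seed), method = method,
         curve_medium = curve_medium, mc = mc),
    class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> '%s': %s, d0 = %g mm, %d pair(s), %d inclusion(s), pitch %g mm\n",
    x$name, x$method, x$d0, length(x$pairs), length(x$inclusions),
    x$grid$pitch))
  invisible(x)
}

scene_to_list <- function(scene) {
  inc_to_list <- function(inc) {
    l <- unclass(inc)
    if (!is.null(l$vertices)) l$vertices <- apply(l$vertices, 1, as.list)
    l
  }
  list(name = scene$name,
       medium = list(mu_a0 = scene$medium$mu_a0,
                     mu_s0_prime = scene$medium$mu_s0_prime,
                     convention = scene$medium$convention),
       curve_medium = list(mu_a0 = scene$curve_medium$mu_a0,
                           mu_s0_prime = scene$curve_medium$mu_s0_prime,
                           convention = scene$curve_medium$convention),
       d0 = scene$d0, pairs = lapply(scene$pairs, as.numeric),
       grid = scene$grid, arrangement = scene$arrangement,
       inclusions = lapply(scene$inclusions, inc_to_list),
       noise_sigma = scene$noise_sigma, seed = scene$seed,
       method = scene$method, mc = scene$mc)
}

list_to_scene <- function(l) {
  list_to_inc <- function(il) {
    shape <- il$shape
    switch(shape,
      point = inclusion_point(unlist(il$center), il$strength),
      sphere = inclusion_sphere(unlist(il$center), il$size, il$delta_mu_a),
      cube = inclusion_cube(unlist(il$center), il$size, il$delta_mu_a),
      cylinder = inclusion_cylinder(unlist(il$p1), unlist(il$p2), il$size,
                                    il$delta_mu_a),
      polyline = inclusion_polyline(
        do.call(rbind, lapply(il$vertices, unlist)), il$size, il$delta_mu_a),
      stop("unknown inclusion shape in scene: ", shape))
  }
  scene_spec(
    name = l$name,
    medium = optical_medium(l$medium$mu_a0, l$medium$mu_s0_prime,
                            convention = l$medium$convention),
    d0 = l$d0, pairs = lapply(l$pairs, unlist),
    grid = lapply(l$grid, unlist),
    inclusions = inclusion_set(lapply(l$inclusions, list_to_inc)),
    arrangement = l$arrangement, noise_sigma = l$noise_sigma,
    seed = l$seed, method = l$method,
    curve_medium = optical_medium(l$curve_medium$mu_a0,
                                  l$curve_medium$mu_s0_prime,
                                  convention = l$curve_medium$convention),
    mc = l$mc)
}

#' Write / read a scene specification as YAML
#'
#' @param scene a [scene_spec()].
#' @param path YAML file path.
#' @return `write_scene`: `path` invisibly; `read_scene`: a `scene_spec`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_spec"))
  yaml::write_yaml(scene_to_list(scene), path, precision = 15)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  list_to_scene(yaml::read_yaml(path))
}

# rod through `center_xy` at depth z, making `angle_deg` with the +y axis,
# long enough to span the scan field with margin
rod_through <- function(center_xy, z, angle_deg, half_len, diameter,
                        delta_mu_a, z2 = z) {
  th <- angle_deg * pi / 180
  dir <- c(sin(th), cos(th))
  p1 <- c(center_xy - half_len * dir, z)
  p2 <- c(center_xy + half_len * dir, z2)
  inclusion_cylinder(p1, p2, diameter, delta_mu_a)
}

#' Built-in synthetic fixtures
#'
#' Emits scenes reproducing the package's reference experiments: single
#' 3.5 mm rods at a configurable depth in a 65 mm medium (liquid-phantom
#' conditions: background 0.005 / 7 per cm, detector offset 19.3 mm),
#' rotated and tilted rods, rods crossing at depths 30 and 45.8 mm (angles
#' 0 or 30 and -20 degrees from +y), curved vessel-like polylines at 16 and
#' 48.5 mm, and the Monte Carlo configurations (40 mm slab, background
#' 0.05 / 5 per cm, 6 mm spheres twenty times more absorbing than the
#' background at depths 12 and 28 mm, singly or lined into two crossing
#' rods). Inclusion absorption contrast defaults to twenty times the
#' background. All parameters can be overridden through `params`.
#'
#' @param name one of `"single_rod_depth"`, `"rotated_rod"`,
#'   `"tilted_rod"`, `"crossing_rods"`, `"mc_spheres"`,
#'   `"mc_crossing_rods"`, `"vessel_pair"`.
#' @param params named list of overrides (e.g. `depth`, `angle`, `pitch`,
#'   `photons`, `noise_sigma`).
#' @param seed integer seed stored in the scene.
#' @return a [scene_spec()].
#' @export
make_fixture <- function(name, params = list(), seed = 1L) {
  valid <- c("single_rod_depth", "rotated_rod", "tilted_rod",
             "crossing_rods", "mc_spheres", "mc_crossing_rods", "vessel_pair")
  if (!name %in% valid)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  p <- function(key, default) params[[key]] %||% default

  phantom <- optical_medium(per_cm(0.005), per_cm(7))
  phantom_curve <- optical_medium(per_cm(0.005), per_cm(5))
  mc_medium <- optical_medium(per_cm(0.05), per_cm(5))
  rod_d <- 3.5
  dmua_phantom <- 19 * phantom$mu_a0   # inclusion 20x background
  dmua_mc <- 19 * mc_medium$mu_a0      # mu_a = 1 /cm vs 0.05 /cm background

  switch(name,
    single_rod_depth = scene_spec(
      name = name, medium = phantom, d0 = 65,
      pairs = list(c(19.3, 0)),
      grid = list(x = p("xlim", c(-20, 20)), y = p("ylim", c(-14, 14)),
                  pitch = p("pitch", 1)),
      inclusions = inclusion_set(rod_through(
        c(0, 0), p("depth", 32.5), p("angle", 0), 70, rod_d,
        p("delta_mu_a", dmua_phantom))),
      noise_sigma = p("noise_sigma", 0), seed = seed,
      curve_medium = phantom_curve),
    rotated_rod = scene_spec(
      name = name, medium = phantom, d0 = 65,
      pairs = list(c(19.3, 0), c(0, 19.3)),
      grid = list(x = p("xlim", c(-20, 20)), y = p("ylim", c(-20, 20)),
                  pitch = p("pitch", 1)),
      inclusions = inclusion_set(rod_through(
        c(0, 0), p("depth", 30), p("angle", 30), 70, rod_d,
        p("delta_mu_a", dmua_phantom))),
      noise_sigma = p("noise_sigma", 0), seed = seed,
      curve_medium = phantom_curve),
    tilted_rod = scene_spec(
      name = name, medium = phantom, d0 = 65,
      pairs = list(c(19.3, 0), c(0, 19.3)),
      grid = list(x = p("xlim", c(-20, 20)), y = p("ylim", c(-20, 20)),
                  pitch = p("pitch", 1)),
      inclusions = inclusion_set(rod_through(
        c(0, 0), p("z1", 25), p("angle", 20), 70, rod_d,
        p("delta_mu_a", dmua_phantom), z2 = p("z2", 45))),
      noise_sigma = p("noise_sigma", 0), seed = seed,
      curve_medium = phantom_curve),
    crossing_rods = scene_spec(
      name = name, medium = phantom, d0 = 65,
      pairs = list(c(19.3, 0), c(0, 19.3)),
      grid = list(x = p("xlim", c(-22, 22)), y = p("ylim", c(-22, 22)),
                  pitch = p("pitch", 1)),
      inclusions = inclusion_set(
        rod_through(c(0, 0), p("depth1", 30), p("angle1", 30), 70, rod_d,
                    p("delta_mu_a", dmua_phantom)),
        rod_through(c(0, 0), p("depth2", 45.8), p("angle2", -20), 70, rod_d,
                    p("delta_mu_a", dmua_phantom))),
      noise_sigma = p("noise_sigma", 0), seed = seed,
      curve_medium = phantom_curve),
    vessel_pair = scene_spec(
      name = name, medium = phantom, d0 = 65,
      pairs = list(c(19.3, 0), c(0, 19.3)),
      grid = list(x = p("xlim", c(-25, 25)), y = p("ylim", c(-20, 20)),
                  pitch = p("pitch", 1)),
      inclusions = inclusion_set(
        inclusion_polyline(cbind(
          x = c(-30, -15, -5, 5, 15, 30), y = c(-14, -8, -2, 3, 10, 14),
          z = p("depth_deep", 48.5)), rod_d,
          p("delta_mu_a", dmua_phantom)),
        inclusion_polyline(cbind(
          x = c(-30, -12, 0, 12, 30), y = c(14, 10, 6, 9, 2),
          z = p("depth_shallow", 16)), rod_d,
          p("delta_mu_a", dmua_phantom))),
      noise_sigma = p("noise_sigma", 0), seed = seed,
      curve_medium = phantom_curve),
    mc_spheres = scene_spec(
      name = name, medium = mc_medium, d0 = 40,
      pairs = list(c(20, 0)),
      grid = list(x = p("xlim", c(-28, 28)), y = c(0, 0),
                  pitch = p("pitch", 0.2)),
      inclusions = inclusion_set(
        inclusion_sphere(c(p("x1", -15), 0, p("z1", 12)), 6,
                         p("delta_mu_a", dmua_mc)),
        inclusion_sphere(c(p("x2", 15), 0, p("z2", 28)), 6,
                         p("delta_mu_a", dmua_mc))),
      seed = seed, method = "mc",
      mc = list(photons = p("photons", 4e6),
                det_radius = p("det_radius", 3),
                boundaries = p("boundaries", "open"),
                source = p("source", "isotropic"))),
    mc_crossing_rods = scene_spec(
      name = name, medium = mc_medium, d0 = 40,
      pairs = list(c(20, 0)),
      grid = list(x = p("xlim", c(-16, 16)), y = p("ylim", c(-16, 16)),
                  pitch = p("pitch", 2)),
      inclusions = inclusion_set(
        rod_through(c(0, 0), p("z1", 12), p("angle1", 20), 27, 6, dmua_mc),
        rod_through(c(0, 0), p("z2", 28), p("angle2", -20), 27, 6, dmua_mc)),
      seed = seed, method = "mc",
      mc = list(photons = p("photons", 6e6),
                det_radius = p("det_radius", 3),
                boundaries = p("boundaries", "open"),
                source = p("source", "isotropic"))))
}
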