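test_that("per-pair depths come element-wise through the curve", {
  cv <- curve40()
  v <- matrix(0L, 5, 9); v[3, c(2, 5, 8)] <- 1L
  sk <- skeleton_image(v, 0.5)
  oth <- skeleton_image(v, 0.5)
  am <- alpha_map(sk, oth, c(13, 0))
  z <- pair_depth(am, cv)
  expect_equal(z[3, c(2, 5, 8)], c(0, 0, 0))    # alpha 0 -> z 0
  expect_true(all(is.na(z[v == 0L])))
  am$alpha[3, 2] <- 0.5
  expect_equal(pair_depth(am, cv)[3, 2], 20, tolerance = 1e-6)
})

test_that("weighted fusion reduces correctly in the standard cases", {
  expect_equal(fuse_depths(c(10, 30), c(1, 1)), 20)          # plain mean
  expect_equal(fuse_depths(c(10, 30), c(1, 0)), 10)          # single pair
  expect_equal(fuse_depths(c(10, NA), c(1, NA)), 10)         # degenerate n=1
  expect_true(is.na(fuse_depths(c(NA, NA), c(1, 1))))
  f <- fuse_depths(c(10, 30), c(0, 0))                       # QC fallback
  expect_equal(as.numeric(f), 20)
  expect_true(attr(f, "unweighted"))
  expect_error(fuse_depths(c(1, 2), c(-1, 1)))
  # convexity over random cases
  set.seed(9)
  for (i in 1:25) {
    z <- runif(3, 0, 65); w <- runif(3)
    fz <- fuse_depths(z, w)
    expect_gte(fz, min(z)); expect_lte(fz, max(z))
  }
})

test_that("pair weights favor offsets perpendicular to a rod", {
  pr <- rod_pair(z = 20)   # rod along y
  dx_p <- directional_second_derivative(pr$plus, "x")
  dx_m <- directional_second_derivative(pr$minus, "x")
  dy_p <- directional_second_derivative(pr$plus, "y")
  dy_m <- directional_second_derivative(pr$minus, "y")
  sk <- skeletonize(second_derivative_image(pr$plus))
  px <- which(sk$values == 1L, arr.ind = TRUE)
  px <- px[which.min(abs(px[, 1] - nrow(sk$values) / 2)), ]
  wx <- pair_weight(dx_p, dx_m, px, 0.5, c(20, 0), pr$plus$pitch)
  wy <- pair_weight(dy_p, dy_m, px, 0.5, c(0, 20), pr$plus$pitch)
  expect_gt(wx, 10 * wy)
  expect_true(is.na(pair_weight(dx_p, dx_m, px, NA, c(20, 0), 1)))
  zero <- matrix(0, nrow(dx_p), ncol(dx_p))
  expect_equal(pair_weight(zero, zero, px, 0.5, c(20, 0), 1), 0)
})

test_that("spherical objects give near-equal x and y weights", {
  geom_x <- pair_geometry(40, c(20, 0))
  geom_y <- pair_geometry(40, c(0, 20))
  sph <- inclusion_set(inclusion_sphere(c(0, 0, 20), 6, 0.02))
  grid <- list(x = seq(-12, 12), y = seq(-12, 12))
  px_pair <- simulate_scan(m05_5, geom_x, sph, grid)
  py_pair <- simulate_scan(m05_5, geom_y, sph, grid)
  dxp <- directional_second_derivative(px_pair$plus, "x")
  dxm <- directional_second_derivative(px_pair$minus, "x")
  dyp <- directional_second_derivative(py_pair$plus, "y")
  dym <- directional_second_derivative(py_pair$minus, "y")
  skx <- skeletonize(second_derivative_image(px_pair$plus))
  ctr <- which(skx$values == 1L, arr.ind = TRUE)
  ctr <- ctr[which.min(abs(ctr[, 1] - 13) + abs(ctr[, 2] - 13)), ]
  wx <- pair_weight(dxp, dxm, ctr, 0.5, c(20, 0), 1)
  # the y pair sees the mirrored geometry: same pixel role transposed
  wy <- pair_weight(t(dyp), t(dym), rev(ctr), 0.5, c(20, 0), 1)
  expect_equal(wx, wy, tolerance = 0.05)
})

test_that("variable-bin histograms conserve pixel counts", {
  cv <- curve40()
  q <- 0.5 / 13
  ks <- 0:26
  zs <- invert_alpha(cv, pmin(ks * q, 1))
  h <- depth_histogram(zs, cv, 0.5, 13)
  expect_equal(nrow(h$bins), 27L)
  expect_equal(sum(h$bins$count), 27L)
  expect_equal(sum(h$bins$density * (h$bins$z_hi - h$bins$z_lo)), 27)
  expect_true(all(diff(h$bins$z_lo) > 0))
  # uniform alpha occupancy yields one count per bin (change of variables)
  expect_equal(h$bins$count, rep(1L, 27))
  # nonuniform widths: the curve is steep near the plates, so one alpha
  # quantum spans more depth there than at mid-depth
  w <- h$bins$z_hi - h$bins$z_lo
  expect_gt(w[2], w[14])
  # all mass in one bin
  h1 <- depth_histogram(rep(invert_alpha(cv, 13 * q), 50), cv, 0.5, 13)
  expect_equal(max(h1$bins$count), 50L)
  expect_equal(sum(h1$bins$count), 50L)
})

test_that("depth classes partition the matched pixels", {
  z <- c(runif(30, 0, 15), runif(20, 15, 28), runif(10, 41, 55))
  cf <- depth_class_fractions(z, c(0, 15, 28, 41, 55))
  expect_equal(sum(cf$count), 60L)
  expect_equal(sum(cf$fraction), 1)
  expect_equal(cf$count[1], 30L)
  expect_equal(cf$count[4], 10L)
})

test_that("two resolvable rods keep their individual alphas when combined", {
  geom <- pair_geometry(65, c(19.3, 0))
  mk_rod <- function(xc, z)
    inclusion_cylinder(c(xc, -70, z), c(xc, 70, z), 3.5, 0.0095)
  # separation well beyond deltaD so the rods are laterally resolved
  grid <- list(x = seq(-36, 36), y = seq(-6, 6))
  m <- optical_medium(per_cm(0.005), per_cm(7))
  run_one <- function(incs) {
    pr <- simulate_scan(m, geom, inclusion_set(incs), grid)
    pr <- lapply(pr, interpolate_grid, target_pitch = 0.5)
    sk <- lapply(pr, function(i) skeletonize(second_derivative_image(i)))
    alpha_map(sk$plus, sk$minus, c(19.3, 0))
  }
  a_sep1 <- run_one(list(mk_rod(-17.5, 20)))
  a_sep2 <- run_one(list(mk_rod(17.5, 45)))
  a_both <- run_one(list(mk_rod(-17.5, 20), mk_rod(17.5, 45)))
  # compare on each rod's centerline row (mid-y), left and right half-field
  mid <- (nrow(a_both$alpha) + 1) %/% 2
  half <- ncol(a_both$alpha) %/% 2
  pick <- function(am, cols) {
    a <- am$alpha[mid, cols]
    a[!is.na(a)][1]
  }
  q <- 0.5 / 19.3
  expect_lte(abs(pick(a_both, 1:half) - pick(a_sep1, 1:half)), q + 1e-9)
  expect_lte(abs(pick(a_both, (half + 2):ncol(a_both$alpha)) -
                   pick(a_sep2, (half + 2):ncol(a_both$alpha))), q + 1e-9)
})

test_that("recovered rod depth is orientation independent away from alignment", {
  cv <- build_depth_curve(optical_medium(per_cm(0.005), per_cm(5)), 65, 19.3)
  m <- optical_medium(per_cm(0.005), per_cm(7))
  depth_for <- function(angle) {
    geoms <- list(x = pair_geometry(65, c(19.3, 0)),
                  y = pair_geometry(65, c(0, 19.3)))
    th <- angle * pi / 180
    rod <- inclusion_cylinder(c(-70 * sin(th), -70 * cos(th), 30),
                              c(70 * sin(th), 70 * cos(th), 30), 3.5, 0.0095)
    grid <- list(x = seq(-15, 15), y = seq(-15, 15))
    pairs <- lapply(names(geoms), function(nm) {
      pr <- simulate_scan(m, geoms[[nm]], inclusion_set(rod), grid)
      pr <- lapply(pr, interpolate_grid, target_pitch = 0.5)
      sk <- lapply(pr, function(i) skeletonize(second_derivative_image(i)))
      dvec <- geoms[[nm]]$deltaD_vec
      dirn <- dotdepth:::deltaD_direction(dvec)
      list(amap = alpha_map(sk$plus, sk$minus, dvec),
           deriv_plus = directional_second_derivative(pr$plus, dirn),
           deriv_minus = directional_second_derivative(pr$minus, dirn))
    })
    dm <- fuse_pairs(pairs, cv)
    median(dm$z, na.rm = TRUE)
  }
  zs <- vapply(c(0, 30, 60, 90), depth_for, numeric(1))
  for (z in zs) expect_equal(z, 30, tolerance = 2.5)
})
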