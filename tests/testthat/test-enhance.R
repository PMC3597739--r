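test_that("grid interpolation preserves nodes, planes and dip locations", {
  xs <- seq(-8, 8, by = 2); ys <- seq(-4, 4, by = 2)
  img <- field_image(function(y, x) 10 + 0.3 * x + 0.1 * y, xs, ys)
  expect_identical(interpolate_grid(img, 2), img)          # identity
  fine <- interpolate_grid(img, 0.5)
  fx <- seq(-8, 8, by = 0.5); fy <- seq(-4, 4, by = 0.5)
  expect_equal(fine$values, outer(fy, fx, function(y, x) 10 + 0.3 * x + 0.1 * y),
               tolerance = 1e-9)                           # linear field exact
  expect_equal(fine$values[seq(1, 17, 4), seq(1, 33, 4)], img$values)
  # Gaussian dip with off-node center localized within 0.5 px of truth
  dip <- field_image(function(y, x) 1 - 0.5 * exp(-((x - 0.7)^2 + y^2) / 18),
                     xs, ys)
  fd <- interpolate_grid(dip, 0.5)
  i0 <- which(fd$values == min(fd$values), arr.ind = TRUE)[1, ]
  expect_lt(abs((fx[i0[2]]) - 0.7), 0.5 * 0.5 + 1e-9)
  expect_error(interpolate_grid(img, 3))                   # coarser refused
  expect_error(interpolate_grid(img, 0.1))                 # factor > 16
})

test_that("directional second derivatives are exact on quadratics", {
  xs <- seq(-5, 5); ys <- seq(-3, 3)
  cvt <- 0.01
  img <- field_image(function(y, x) 1 / (1 + cvt / 2 * x^2), xs, ys)
  d2 <- directional_second_derivative(img, "x")
  expect_equal(d2[2:6, 2:10], matrix(cvt, 5, 9), tolerance = 1e-12)
  expect_equal(d2[, 1], rep(0, 7))                         # borders zeroed
  expect_equal(directional_second_derivative(img, "y")[3, 4], 0)
  # diagonal step is pitch * sqrt(2)
  imgd <- field_image(function(y, x) 1 / (1 + 0.005 * (x + y)^2), xs, ys)
  # along the diagonal (x+y) changes by 2 per unit diagonal-step/sqrt(2):
  # d2/du2 of 0.005 (x+y)^2 is 0.005 * 2 * (sqrt(2))^2 = 0.02
  d45 <- directional_second_derivative(imgd, "+45")
  expect_equal(d45[4, 6], 0.02, tolerance = 1e-6)
  flat <- field_image(function(y, x) rep(7, length(x)), xs, ys)
  expect_equal(directional_second_derivative(flat, "x"),
               matrix(0, 7, 11))
  bad <- flat; bad$values[2, 2] <- -1
  expect_error(directional_second_derivative(bad, "x"), "positive")
})

test_that("curvature image is the directional minimum with argmin labels", {
  pr <- rod_pair(z = 20)
  cv <- second_derivative_image(pr$plus)
  for (d in cv$directions)
    expect_true(all(cv$values <= directional_second_derivative(pr$plus, d) + 1e-12))
  # rod along y: argmin direction is x along the rod ridge
  ridge <- which(cv$values == min(cv$values), arr.ind = TRUE)[1, ]
  expect_equal(cv$directions[cv$argmin[ridge[1], ridge[2]]], "x")
  flat <- field_image(function(y, x) rep(1, length(x)), seq(-5, 5), seq(-5, 5))
  expect_equal(second_derivative_image(flat)$values, matrix(0, 11, 11))
  # single-line scans fall back to the feasible directions
  line <- scan_image(matrix(c(2, 1, 2, 3, 4), 1), pitch = 1, origin = c(0, 0))
  cv1 <- second_derivative_image(line)
  expect_equal(cv1$directions, "x")
})

test_that("skeletons trace ridge centerlines one pixel wide", {
  pr <- rod_pair(z = 20)  # rod at x alpha-shifted by -5 in the plus image
  sk <- skeletonize(second_derivative_image(pr$plus))
  idx <- which(sk$values == 1L, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  xs_on <- unique(sk$origin[1] + (idx[, 2] - 1) * sk$pitch)
  expect_length(xs_on, 1L)                      # 1 px wide vertical line
  expect_equal(xs_on, -5, tolerance = 1)        # alpha = 0.5 shift of 10/2
  flat <- field_image(function(y, x) rep(1, length(x)), seq(-5, 5), seq(-5, 5))
  expect_equal(skeletonize(second_derivative_image(flat))$n_on, 0L)
})

test_that("two parallel rods give two skeleton components", {
  geom <- pair_geometry(40, c(20, 0))
  incs <- inclusion_set(
    inclusion_cylinder(c(-8, -60, 20), c(-8, 60, 20), 3, 0.01),
    inclusion_cylinder(c(8, -60, 20), c(8, 60, 20), 3, 0.01))
  pr <- simulate_scan(m05_5, geom, incs,
                      list(x = seq(-20, 20), y = seq(-5, 5)))
  sk <- skeletonize(second_derivative_image(pr$plus))
  expect_equal(n_components(sk), 2L)
})

test_that("skeletons are translation equivariant and scale/contrast invariant", {
  mk <- function(xc, dmua = 0.01, scale = 1) {
    geom <- pair_geometry(40, c(20, 0))
    pr <- simulate_scan(m05_5, geom,
      inclusion_set(inclusion_cylinder(c(xc, -60, 20), c(xc, 60, 20), 3, dmua)),
      list(x = seq(-15, 15), y = seq(-4, 4)))
    img <- pr$plus; img$values <- img$values * scale
    skeletonize(second_derivative_image(img))
  }
  s0 <- mk(0)
  s1 <- mk(1)   # one-pitch translation
  expect_equal(s1$values[, 2:31], s0$values[, 1:30])
  expect_equal(mk(0, scale = 37.5)$values, s0$values)       # intensity scale
  on_px <- function(s) which(s$values == 1L)
  expect_equal(on_px(mk(0, dmua = 0.03)), on_px(s0))         # contrast
})

test_that("gaussian smoothing preserves constants and dip centers", {
  xs <- seq(-10, 10); ys <- seq(-4, 4)
  flat <- field_image(function(y, x) rep(3, length(x)), xs, ys)
  expect_equal(smooth_scan(flat, 3)$values, flat$values, tolerance = 1e-12)
  dip <- field_image(function(y, x) 1 - 0.4 * exp(-(x - 2)^2 / 8), xs, ys)
  sm <- smooth_scan(dip, 3)
  expect_equal(xs[which.min(sm$values[3, ])], 2)
  expect_gt(min(sm$values), min(dip$values))   # smoothing shrinks the dip
})
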