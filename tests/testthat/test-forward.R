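test_that("Green's function has the closed infinite-medium form", {
  m0 <- optical_medium(0, 0.5)
  r <- c(5, 10, 40)
  expect_equal(greens_function(m0, r), 1 / (4 * pi * m0$D_coef * r))
  m <- optical_medium(0.005, 0.5)
  expect_equal(greens_function(m, 2 * r) / greens_function(m, r),
               exp(-m$mu_eff * r) / 2)
  expect_true(all(diff(greens_function(m, seq(1, 50, by = 1))) < 0))
  expect_error(greens_function(m, 0))
  expect_error(greens_function(m, -3))
})

test_that("point Born kernel matches an independent evaluation", {
  m <- optical_medium(0.005, 0.5)
  # independent closed form: -(strength/(4 pi D)) r3/(r1 r2) exp(-mueff(r1+r2-r3))
  val <- relative_perturbation_point(m, c(0, 0, 0), c(0, 0, 40), c(0, 0, 20), 1)
  expect_equal(val, -(1 / (4 * pi * m$D_coef)) * (40 / 400) * exp(0))
  # off-axis case, still independently evaluated
  s <- c(0, 0, 0); d <- c(5, -3, 40); p <- c(2, 1, 13)
  r1 <- sqrt(sum((s - p)^2)); r2 <- sqrt(sum((d - p)^2)); r3 <- sqrt(sum((s - d)^2))
  expect_equal(
    relative_perturbation_point(m, s, d, p, 2.5),
    -(2.5 / (4 * pi * m$D_coef)) * (r3 / (r1 * r2)) * exp(-m$mu_eff * (r1 + r2 - r3)))
  expect_equal(relative_perturbation_point(m, s, d, p, 0), 0)
  expect_error(relative_perturbation_point(m, s, d, s, 1), "coincides")
})

test_that("point kernel is reciprocal and laterally extremal on the axis", {
  m <- optical_medium(0.005, 0.5)
  s <- c(0, 0, 0); d <- c(0, 0, 40); p <- c(1, 2, 25)
  expect_equal(relative_perturbation_point(m, s, d, p, 1),
               relative_perturbation_point(m, d, s, p, 1))
  on_axis <- abs(relative_perturbation_point(m, s, d, c(0, 0, 20), 1))
  for (dx in c(0.5, 2, 5))
    expect_lt(abs(relative_perturbation_point(m, s, d, c(dx, 0, 20), 1)), on_axis)
})

test_that("extended kernel converges to the point kernel and in step", {
  m <- optical_medium(0.005, 0.5)
  s <- c(0, 0, 0); d <- c(0, 0, 40)
  cube1 <- inclusion_cube(c(0, 0, 20), 1, 1)   # V * dmua = 1 mm^2
  v_ext <- relative_perturbation_extended(m, s, d, cube1, quadrature_step = 0.25)
  v_pt <- relative_perturbation_point(m, s, d, c(0, 0, 20), 1)
  expect_equal(v_ext, v_pt, tolerance = 0.01)
  sph <- inclusion_sphere(c(3, 1, 15), 6, 0.01)
  vh <- relative_perturbation_extended(m, s, d, sph, quadrature_step = 1)
  vh2 <- relative_perturbation_extended(m, s, d, sph, quadrature_step = 0.5)
  expect_lt(abs(vh2 - vh) / abs(vh2), 0.005)
  expect_error(relative_perturbation_extended(m, s, d, sph, quadrature_step = 4))
})

test_that("simulated scans are constant without inclusions and add linearly", {
  geom <- pair_geometry(40, c(20, 0))
  grid <- list(x = seq(-10, 10, by = 2), y = seq(-4, 4, by = 2))
  empty <- simulate_scan(m05_5, geom, inclusion_set(), grid)
  expect_equal(diff(range(empty$plus$values)), 0)
  expect_equal(diff(range(empty$minus$values)), 0)
  expect_error(simulate_scan(m05_5, geom, inclusion_set(), list(x = numeric(0), y = 0)))

  pa <- inclusion_point(c(-3, 0, 15), 1)
  pb <- inclusion_point(c(4, 1, 30), 1)
  ra <- simulate_scan(m05_5, geom, inclusion_set(pa), grid)
  rb <- simulate_scan(m05_5, geom, inclusion_set(pb), grid)
  rab <- simulate_scan(m05_5, geom, inclusion_set(pa, pb), grid)
  I0 <- empty$plus$values[1, 1]
  expect_equal(rab$plus$values / I0 - 1,
               (ra$plus$values / I0 - 1) + (rb$plus$values / I0 - 1))
})

test_that("simulated scans are translation equivariant", {
  geom <- pair_geometry(40, c(20, 0))
  grid <- list(x = seq(-12, 12, by = 2), y = seq(-6, 6, by = 2))
  p0 <- simulate_scan(m05_5, geom, inclusion_set(inclusion_point(c(0, 0, 18), 1)), grid)
  p1 <- simulate_scan(m05_5, geom, inclusion_set(inclusion_point(c(2, 2, 18), 1)), grid)
  # shifting the inclusion by one pitch shifts the image by one pixel
  expect_equal(p1$plus$values[2:7, 2:13], p0$plus$values[1:6, 1:12])
  expect_equal(p1$minus$values[2:7, 2:13], p0$minus$values[1:6, 1:12])
})

test_that("image minima shift grows with depth and matches the depth curve", {
  geom <- pair_geometry(40, c(20, 0))
  xs <- seq(-22, 22, by = 0.5)
  shift_at <- function(z) {
    r <- simulate_scan(m05_5, geom,
                       inclusion_set(inclusion_point(c(0, 0, z), 1)),
                       list(x = xs, y = 0))
    dotdepth:::refine_minimum(xs, r$minus$values[1, ]) -
      dotdepth:::refine_minimum(xs, r$plus$values[1, ])
  }
  zs <- c(6, 12, 20, 28, 34)
  shifts <- vapply(zs, shift_at, numeric(1))
  expect_true(all(diff(shifts) > 0))
  expect_equal(shifts[3] / 20, 0.5, tolerance = 1e-3)   # mid-depth symmetry
  # z = 12, d0 = 40: shift/deltaD agrees with the depth curve within a step
  expect_equal(shifts[2] / 20, depth_to_alpha(curve40(), 12),
               tolerance = 0.5 / 20)
})
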