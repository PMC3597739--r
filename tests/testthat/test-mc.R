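test_that("a fixed seed reproduces the transport bitwise", {
  cfg <- mc_config(m05_5, 40, inclusion_set(inclusion_sphere(c(0, 0, 15), 6, 0.05)),
                   scan_x = seq(-6, 6, by = 2), scan_y = 0,
                   det_offsets = pair_geometry(40, c(20, 0)),
                   det_radius = 5, photons = 2e5, seed = 99)
  r1 <- run_mc_scan(cfg)
  r2 <- run_mc_scan(cfg)
  expect_identical(r1$images$D_plus$values, r2$images$D_plus$values)
  expect_identical(r1$bookkeeping, r2$bookkeeping)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(run_mc_scan(cfg2)$images$D_plus$values,
                         r1$images$D_plus$values))
})

test_that("launched weight is conserved across all termination channels", {
  for (bd in c("slab", "open")) {
    cfg <- mc_config(m05_5, 20, inclusion_set(),
                     scan_x = 0, scan_y = 0,
                     det_offsets = matrix(c(0, 0), 1), det_radius = 5,
                     photons = 5e4, seed = 3, boundaries = bd)
    run <- run_mc_scan(cfg)
    expect_lt(mc_energy_residual(run), 1e-9)
    if (bd == "open") expect_equal(run$bookkeeping$escaped, 0)
    else expect_gt(run$bookkeeping$escaped, 0)
  }
})

test_that("homogeneous transmittance is scan invariant and falls with musp and offset", {
  geom <- pair_geometry(30, c(16, 0))
  base <- mc_config(optical_medium(0, 0.5), 30, inclusion_set(),
                    scan_x = seq(-4, 4, by = 2), scan_y = 0,
                    det_offsets = geom, det_radius = 5, photons = 2e5, seed = 17)
  r <- run_mc_scan(base)
  expect_equal(diff(range(r$images$D_plus$values)), 0)   # no inclusions
  # mu_a = 0: doubling mu_s' reduces transmittance
  cfg2 <- mc_config(optical_medium(0, 1.0), 30, inclusion_set(),
                    scan_x = seq(-4, 4, by = 2), scan_y = 0,
                    det_offsets = geom, det_radius = 5, photons = 2e5, seed = 17)
  expect_lt(run_mc_scan(cfg2)$T_hom[1], r$T_hom[1])
  # transmittance decreases with lateral detector offset
  offs <- rbind(c(0, 0), c(5, 0), c(10, 0), c(15, 0))
  cfg3 <- mc_config(m05_5, 30, inclusion_set(), scan_x = 0, scan_y = 0,
                    det_offsets = offs, det_radius = 4, photons = 4e5, seed = 23)
  expect_true(all(diff(run_mc_scan(cfg3)$T_hom) < 0))
})

test_that("a Born-regime sphere dip matches the diffusion forward model", {
  # weak absorber: first-order regime where the Born kernel is valid
  m <- m05_5
  geom <- pair_geometry(40, c(20, 0))
  xs <- seq(-12, 12, by = 1)
  sph <- inclusion_set(inclusion_sphere(c(0, 0, 20), 6, 0.01))
  cfg <- mc_config(m, 40, sph, scan_x = xs, scan_y = 0,
                   det_offsets = geom, det_radius = 4, photons = 1.5e6,
                   seed = 8, boundaries = "open", source = "isotropic")
  run <- run_mc_scan(cfg)
  rel_mc <- 1 - min(run$images$D_plus$values[1, ]) / run$T_hom[1]
  dif <- simulate_scan(m, geom, sph, list(x = xs, y = 0))
  rel_dif <- 1 - min(dif$plus$values[1, ]) / max(dif$plus$values[1, ])
  expect_equal(rel_mc, rel_dif, tolerance = 0.25)
  # and the dip sits on the correct side of the scan axis for D_plus
  expect_lt(xs[which.min(run$images$D_plus$values[1, ])], 0)
  expect_gt(xs[which.min(run$images$D_minus$values[1, ])], 0)
})

test_that("sparse re-scoring equals brute-force chords over the same paths", {
  m <- m05_5
  geom <- pair_geometry(40, c(20, 0))
  xs <- seq(-4, 4, by = 2)
  sph <- inclusion_set(inclusion_sphere(c(0, 0, 20), 6, 0.095))
  cfg <- mc_config(m, 40, sph, scan_x = xs, scan_y = 0,
                   det_offsets = geom, det_radius = 4, photons = 1e4,
                   seed = 5, boundaries = "open", source = "isotropic")
  run <- run_mc_scan(cfg, return_paths = TRUE)
  p <- run$paths
  chord <- function(ax, ay, az, bx, by, bz, cx, cy, cz, r) {
    dx <- bx - ax; dy <- by - ay; dz <- bz - az
    fx <- ax - cx; fy <- ay - cy; fz <- az - cz
    A <- dx^2 + dy^2 + dz^2
    B <- 2 * (fx * dx + fy * dy + fz * dz)
    C <- fx^2 + fy^2 + fz^2 - r^2
    disc <- B^2 - 4 * A * C
    out <- numeric(length(ax)); ok <- disc > 0 & A > 0
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- pmax((-B[ok] - sq) / (2 * A[ok]), 0)
      t2 <- pmin((-B[ok] + sq) / (2 * A[ok]), 1)
      out[ok] <- pmax(t2 - t1, 0) * sqrt(A[ok])
    }
    out
  }
  Tb <- vapply(xs, function(sx) {
    tot <- 0
    for (i in seq_along(p$w)) {
      ii <- (p$start[i] + 1):(p$start[i] + p$n[i] - 1)
      ln <- chord(p$vx[ii], p$vy[ii], p$vz[ii],
                  p$vx[ii + 1], p$vy[ii + 1], p$vz[ii + 1], -sx, 0, 20, 3)
      tot <- tot + p$w[i] * exp(-0.095 * sum(ln))
    }
    tot / 1e4
  }, numeric(1))
  expect_equal(run$images$D_plus$values[1, ], Tb, tolerance = 1e-12)
})

test_that("a mid-depth sphere is recovered at d0/2 within one alpha quantum", {
  cv <- curve40()
  geom <- pair_geometry(40, c(20, 0))
  cfg <- mc_config(m05_5, 40,
                   inclusion_set(inclusion_sphere(c(0, 0, 20), 6, 0.095)),
                   scan_x = seq(-14, 14, by = 1), scan_y = 0,
                   det_offsets = geom, det_radius = 5, photons = 1.5e6,
                   seed = 4, boundaries = "open", source = "isotropic")
  ex <- mc_depth_experiment(cfg, cv,
                            objects = list(list(name = "mid", point = c(0, 0))),
                            smooth_fwhm = 4)
  # one alpha quantum (1 mm pixels) spans about 2 mm in z at mid depth
  expect_equal(ex$summary$valley_z[1], 20, tolerance = 2.5)
  expect_lt(mc_energy_residual(ex$run), 1e-9)
})
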