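test_that("scan TSV round trip is lossless including metadata", {
  geom <- pair_geometry(40, c(20, 0))
  img <- scan_image(matrix(runif(12, 0.5, 2), 3, 4), pitch = 2,
                    origin = c(-4, -2), detector = "D_minus",
                    geometry = geom, medium = m05_5)
  path <- tempfile(fileext = ".tsv")
  write_scan(img, path)
  back <- read_scan(path)
  expect_identical(back$values, img$values)        # bitwise
  expect_equal(back$pitch, 2)
  expect_equal(back$origin, c(-4, -2))
  expect_equal(back$detector, "D_minus")
  expect_equal(back$geometry$deltaD_vec, c(20, 0))
  expect_equal(back$medium$mu_eff, m05_5$mu_eff)
})

test_that("schema errors name the missing key", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# dotdepth scan v1", "# origin_mm: 0 0", "# detector: D_plus",
               "1\t2", "3\t4"), path)
  expect_error(read_scan(path), "pitch_mm")
})

test_that("grid shape follows the declared extent and pitch", {
  sc <- make_fixture("single_rod_depth", params = list(pitch = 2))
  imgs <- simulate_scene(sc)
  expect_equal(dim(imgs[[1]]$plus$values),
               c(length(seq(-14, 14, by = 2)), length(seq(-20, 20, by = 2))))
  expect_equal(imgs[[1]]$plus$pitch, 2)
})

test_that("TIFF export writes the grid and a metadata sidecar", {
  img <- scan_image(matrix(runif(20, 0.1, 0.9), 4, 5), pitch = 1,
                    origin = c(0, 0))
  path <- tempfile(fileext = ".tif")
  write_scan_tiff(img, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$pitch_mm, 1)
  back <- tiff::readTIFF(path)
  expect_equal(back, img$values, tolerance = 1e-6)
})

test_that("alpha maps serialize with NaN sentinel and JSON summary", {
  v <- matrix(0L, 4, 30); v[2, c(3, 7)] <- 1L
  am <- alpha_map(skeleton_image(v, 0.5), skeleton_image(v, 0.5), c(13, 0))
  path <- tempfile(fileext = ".tsv")
  write_alpha_map(am, path)
  lines <- readLines(path)
  expect_true(any(grepl("no_match: NaN", lines)))
  smry <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(smry$match_fraction, 1)
  expect_equal(smry$n_skeleton, 2)
})

test_that("scenes round-trip through YAML", {
  sc <- make_fixture("crossing_rods", seed = 12)
  path <- tempfile(fileext = ".yaml")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_equal(back$d0, sc$d0)
  expect_equal(back$pairs, sc$pairs)
  expect_equal(back$seed, sc$seed)
  expect_equal(back$medium$mu_a0, sc$medium$mu_a0)
  expect_equal(length(back$inclusions), 2L)
  expect_equal(back$inclusions[[1]]$p1, sc$inclusions[[1]]$p1)
  expect_equal(back$inclusions[[2]]$delta_mu_a, sc$inclusions[[2]]$delta_mu_a)
  # polyline scenes too
  vp <- make_fixture("vessel_pair")
  write_scene(vp, path)
  expect_equal(read_scene(path)$inclusions[[1]]$vertices,
               vp$inclusions[[1]]$vertices, ignore_attr = TRUE)
})

test_that("fixtures encode the reference geometries", {
  cr <- make_fixture("crossing_rods")
  zs <- sort(vapply(cr$inclusions, function(i) i$p1[3], numeric(1)))
  expect_equal(zs, c(30, 45.8))
  vp <- make_fixture("vessel_pair")
  zv <- sort(vapply(vp$inclusions, function(i) i$vertices[1, 3], numeric(1)))
  expect_equal(zv, c(16, 48.5))
  expect_equal(sqrt(sum(vp$pairs[[1]]^2)), 19.3)
  ms <- make_fixture("mc_spheres")
  expect_equal(ms$medium$mu_a0, 0.005)
  expect_equal(vapply(ms$inclusions, function(i) i$center[3], numeric(1)),
               c(12, 28))
  expect_equal(vapply(ms$inclusions, function(i) i$delta_mu_a, numeric(1)),
               rep(19 * 0.005, 2))                    # 20x background
  expect_error(make_fixture("nope"), "single_rod_depth")
})

test_that("noise realizations are reproducible from the scene seed", {
  sc <- make_fixture("single_rod_depth",
                     params = list(noise_sigma = 0.01, pitch = 2), seed = 33)
  i1 <- simulate_scene(sc)
  i2 <- simulate_scene(sc)
  expect_identical(i1[[1]]$plus$values, i2[[1]]$plus$values)
  sc2 <- make_fixture("single_rod_depth",
                      params = list(noise_sigma = 0.01, pitch = 2), seed = 34)
  expect_false(identical(simulate_scene(sc2)[[1]]$plus$values,
                         i1[[1]]$plus$values))
})

test_that("an empty scene runs through the pipeline with a warning", {
  sc <- scene_spec("empty", m05_5, 40, pairs = list(c(20, 0)),
                   grid = list(x = c(-8, 8), y = c(-4, 4), pitch = 2),
                   inclusions = inclusion_set())
  expect_warning(res <- run_pipeline(sc), "empty depth map")
  expect_null(res$depth_map)
  expect_true(is.na(res$report$match_fraction[1]))
  expect_equal(res$report$manifest$reference_detector, "D_plus")
})

test_that("pipeline runs are deterministic and fully manifested", {
  sc <- make_fixture("single_rod_depth",
                     params = list(noise_sigma = 0.005, pitch = 2,
                                   xlim = c(-16, 16), ylim = c(-8, 8)),
                     seed = 5)
  r1 <- run_pipeline(sc, target_pitch = 1)
  r2 <- run_pipeline(sc, target_pitch = 1)
  expect_identical(r1$depth_map$z, r2$depth_map$z)
  man <- r1$report$manifest
  for (key in c("seed", "method", "deltaD_mm", "arrangement", "medium",
                "curve_medium", "target_pitch_mm", "window_mm", "noise_floor",
                "noise_sigma", "quadrature_step_mm", "curve_z_step_mm",
                "localization", "reference_detector", "tie_break"))
    expect_false(is.null(man[[key]]))
  expect_s3_class(r1$report$class_fractions, "data.frame")
})
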