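# core_io: stack container, TIFF round trips, MIP, ROI, config, artifacts.

roles3 <- c("membrane", "nuclear_unconverted", "nuclear_converted")

test_that("channel_stack normalises axes and validates its contract", {
  m <- matrix(runif(6 * 8), 6, 8)
  st <- channel_stack(m, "nuclear_converted")
  expect_equal(dim(st$pixels), c(1, 1, 1, 6, 8))
  expect_equal(st$pixels[1, 1, 1, , ], m)

  # 2-channel 2D image with an explicit axis tag
  arr <- array(runif(2 * 6 * 8), dim = c(2, 6, 8))
  st2 <- channel_stack(arr, roles3[2:3], axes = "cyx")
  expect_equal(dim(st2$pixels), c(1, 2, 1, 6, 8))
  expect_equal(st2$pixels[1, 2, 1, , ], arr[2, , ])

  # 5-frame single-channel time series
  ts <- array(runif(5 * 4 * 4), dim = c(5, 4, 4))
  st3 <- channel_stack(ts, "nuclear_converted", axes = "tyx")
  expect_equal(dim(st3$pixels), c(5, 1, 1, 4, 4))

  expect_error(channel_stack(arr, roles3, axes = "cyx"), "channel_roles")
  expect_error(channel_stack(-m, "membrane"), ">= 0")
  expect_error(channel_stack(m, "membrane", pixel_size_um = c(1, 0, 1)),
               "positive")
  expect_error(channel_stack(arr, c("membrane", "membrane"), axes = "cyx"),
               "unique")
})

test_that("stack TIFF round trip restores geometry, roles and metadata", {
  arr <- array(round(runif(2 * 3 * 2 * 5 * 7) * 1000) / 4,
               dim = c(2, 3, 2, 5, 7))
  st <- channel_stack(arr, roles3, pixel_size_um = c(2, 0.5, 0.5),
                      time_step_min = 15)
  path <- withr::local_tempfile(fileext = ".tif")
  write_outputs(st, path)
  st2 <- read_stack(path)
  expect_equal(st2$pixels, st$pixels, tolerance = 1e-6)
  expect_identical(st2$channel_roles, roles3)
  expect_equal(st2$pixel_size_um, c(2, 0.5, 0.5))
  expect_equal(st2$time_step_min, 15)
  # role count mismatch against embedded metadata
  expect_error(read_stack(path, roles = roles3[1:2]), "roles length")
})

test_that("label mask TIFF round trip is exact and validated", {
  mask <- matrix(0L, 9, 11)
  mask[2:4, 2:4] <- 1L
  mask[6:8, 5:9] <- 2L
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(mask, path)
  expect_identical(read_label_mask(path)[1, , ], mask)
  expect_error(photolineage:::validate_label_mask(matrix(c(0L, 2L), 1, 2)),
               "contiguous")
})

test_that("project_mip equals the brute-force per-pixel max and is idempotent", {
  # constant planes
  vol <- array(0, dim = c(1, 1, 2, 4, 4))
  vol[1, 1, 1, , ] <- 1
  vol[1, 1, 2, , ] <- 3
  st <- channel_stack(vol, "nuclear_converted")
  expect_true(all(project_mip(st)$pixels == 3))

  # singleton z: identity
  one <- channel_stack(matrix(runif(16), 4, 4), "membrane")
  expect_equal(project_mip(one)$pixels, one$pixels)

  # random 4x4x4 volume vs explicit triple loop
  set.seed(42)
  v <- array(runif(64), dim = c(1, 1, 4, 4, 4))
  stv <- channel_stack(v, "nuclear_converted")
  mip <- project_mip(stv)
  expect_equal(mip$pixels[1, 1, 1, , ], oracle_mip(array(v[1, 1, , , ],
                                                         dim = c(4, 4, 4))))
  expect_equal(project_mip(mip)$pixels, mip$pixels)
})

test_that("apply_roi implements the even-odd rule with kept boundaries", {
  img <- matrix(1, 8, 8)
  sq <- roi_polygon(rbind(c(1, 1), c(1, 5), c(5, 5), c(5, 1)))
  inside <- apply_roi(img, sq)
  expect_equal(sum(inside), 25)  # 5x5 block of kept pixel centres
  outside <- apply_roi(img, roi_polygon(sq$vertices, "keep_outside"))
  # the two senses partition the nonzero pixels
  expect_true(all(inside + outside == img))

  # triangle vs per-pixel brute-force even-odd oracle
  tri <- roi_polygon(rbind(c(0.2, 0.3), c(6.7, 1.1), c(3.1, 7.4)))
  got <- apply_roi(img, tri) > 0
  want <- matrix(FALSE, 8, 8)
  for (y in 1:8) for (x in 1:8)
    want[y, x] <- oracle_pip(y - 1, x - 1, tri$vertices)
  expect_identical(got, want)

  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1), c(0, 0))), "degenerate")
  expect_error(roi_polygon(rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))),
               "simple")
})

test_that("artifact writers round-trip every artifact type", {
  dir <- withr::local_tempdir()
  # nucleus records as CSV
  st <- channel_stack(array(runif(2 * 36), dim = c(2, 6, 6)), roles3[2:3],
                      axes = "cyx")
  mask <- matrix(0L, 6, 6)
  mask[2:3, 2:3] <- 1L
  rec <- measure_nuclei(mask, st)
  p <- file.path(dir, "nuclei.csv")
  write_outputs(rec, p)
  rec2 <- read_nuclei(p)
  expect_equal(as.data.frame(rec2), as.data.frame(rec), tolerance = 1e-12)

  # lineage forest with one division
  fr <- list(data.frame(frame = 1, label = 1, centroid_y_um = 5,
                        centroid_x_um = 5),
             data.frame(frame = 2, label = 1:2, centroid_y_um = c(4, 6),
                        centroid_x_um = c(4, 6)))
  forest <- build_forest(fr, gate_um = 5)
  p <- file.path(dir, "forest.json")
  write_outputs(forest, p)
  forest2 <- read_forest(p)
  expect_equal(forest2$edges, forest$edges)
  expect_equal(summarize_forest(forest2), summarize_forest(forest))

  # mixture model (K = 1, w = 1, mu = 5, sd = 1)
  model <- fit_mixture(rnorm(50, 5, 1), 1)
  p <- file.path(dir, "mixture.json")
  write_outputs(model, p)
  model2 <- read_mixture(p)
  expect_equal(model2$means, model$means)
  expect_equal(model2$weights, model$weights)
  expect_equal(model2$log_likelihood, model$log_likelihood)

  # spatial result
  pts <- cbind(c(1, 2.5, 4, 5.5), c(1, 1, 1, 1))
  sp <- permutation_test(pts, matrix(TRUE, 8, 8), n_perm = 99, seed = 1)
  p <- file.path(dir, "spatial.json")
  write_outputs(sp, p)
  sp2 <- read_spatial(p)
  expect_equal(sp2$p_alignment, sp$p_alignment)
  expect_equal(sp2$alignment_rms, sp$alignment_rms)
})

test_that("pipeline configuration validates before any work", {
  expect_error(pipeline_config(k_min = 3, k_max = 2), "k_min")
  expect_error(pipeline_config(n_perm = 50), "n_perm")
  expect_error(pipeline_config(gate_um = 0), "gate_um")
  expect_error(pipeline_config(restarts = 0), "restarts")
  expect_error(pipeline_config(bright_rule = "best"), "bright_rule")

  # YAML round trip
  cfg <- pipeline_config(seed = 7, k = 3, n_perm = 199)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scenario = "regeneration_7dpa", seed = 7, k = 3,
                        n_perm = 199), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$k, cfg$k)
})
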