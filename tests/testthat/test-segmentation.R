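# segmentation: robust background, threshold components, membrane-guided
# watershed, and evaluation against generator truth.

test_that("estimate_background matches the direct median/MAD formulas", {
  expect_equal(unclass(estimate_background(matrix(10, 5, 5)))[1:2],
               list(level = 10, spread = 0))
  v <- matrix(0, 10, 10)
  v[1] <- 1000
  expect_equal(estimate_background(v)$level, 0)

  set.seed(9)
  frame <- matrix(rexp(32 * 32, 1 / 50), 32, 32)
  bg <- estimate_background(frame)
  expect_equal(bg$level, median(frame))
  expect_equal(bg$spread,
               1.4826 * median(abs(frame - median(frame))))
  excl <- frame > 100
  bg2 <- estimate_background(frame, exclude = excl)
  expect_equal(bg2$level, median(frame[!excl]))
  expect_error(estimate_background(frame, exclude = frame > -1), "excluded")
})

test_that("segment_nuclei thresholds, filters and relabels deterministically", {
  bg <- list(level = 0, spread = 50 / (3 * 1))  # T = 50 with k_bg = 3
  frame <- matrix(0, 20, 20)
  expect_equal(max(segment_nuclei(frame, bg, 3, 1)), 0L)

  frame[2:6, 2:6] <- 100
  frame[10:14, 12:16] <- 100
  lab <- segment_nuclei(frame, bg, 3, 1)
  expect_equal(max(lab), 2L)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  # min_size removes the smaller component
  frame[18, 18] <- 100
  expect_equal(max(segment_nuclei(frame, bg, 3, 5)), 2L)
  expect_equal(max(segment_nuclei(frame, bg, 3, 1)), 3L)
  # threshold monotonicity: raising T never adds foreground pixels
  counts <- vapply(seq(0, 120, by = 10), function(T)
    sum(frame > T), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(segment_nuclei(frame, bg, 0), "k_bg")
})

test_that("detected nuclei track the ground-truth count and positions", {
  sc <- small_regen_scenario(seed = 1)
  sim <- simulate_tissue(sc)
  conv <- sim$stack$pixels[1, 3, 1, , ]
  keep <- (col(conv) - 1) * sc$pixel_size_um >= sc$plane_x_um
  bg <- estimate_background(conv, exclude = !keep)
  work <- conv
  work[!keep] <- 0
  mask <- segment_nuclei(work, bg, 3, 20)
  tc <- sim$truth$cells
  tc <- tc[tc$converted & tc$x_um >= sc$plane_x_um, ]
  expect_lt(abs(max(mask) / nrow(tc) - 1), 0.10)

  rec <- measure_nuclei(mask, sim$stack, bg = list(nuclear_converted = bg))
  ev <- evaluate_segmentation(cbind(rec$centroid_y_um, rec$centroid_x_um),
                              cbind(tc$y_um, tc$x_um),
                              match_radius_um = sc$nuclear_radius_um)
  expect_gte(ev$f1, 0.9)
})

test_that("membrane_guided_split separates touching nuclei, never merges", {
  # dumbbell with a membrane ridge across the neck -> 2 labels
  mask <- matrix(0L, 15, 25)
  mask[5:11, 3:10] <- 1L
  mask[5:11, 10:20] <- 1L
  membrane <- matrix(0, 15, 25)
  membrane[, 10] <- 100
  out <- membrane_guided_split(mask, membrane)
  expect_equal(max(out), 2L)
  expect_identical(out > 0, photolineage:::as_mask3d(mask) > 0)

  # uniformly zero membrane: identity up to relabelling
  flat <- membrane_guided_split(mask, matrix(0, 15, 25))
  expect_equal(max(flat), 1L)
  expect_identical(flat > 0, photolineage:::as_mask3d(mask) > 0)

  expect_error(membrane_guided_split(mask, matrix(0, 5, 5)), "shape")
})

test_that("membrane watershed follows the nearest-centroid partition", {
  # two touching nuclei rendered with a Voronoi membrane between them
  sc <- photo_scenario("regeneration_7dpa", seed = 4, field_um = c(40, 60),
                       psf_sigma_um = 0.5,
                       noise = list(enabled = FALSE, offset = 0,
                                    quantize = FALSE))
  cells <- photolineage:::new_cells(id = 1:2, y_um = c(20, 20),
                                    x_um = c(24, 36), radius_um = 3,
                                    converted_pool = 400,
                                    unconverted_pool = 0,
                                    membrane_pool = 300)
  st <- render_frame(cells, sc)
  conv <- st$pixels[1, 3, 1, , ]
  mask <- segment_nuclei(conv, list(level = 0, spread = 10 / 3), 3, 10)
  expect_equal(max(mask), 1L)  # merged without the membrane
  split <- membrane_guided_split(mask, st$pixels[1, 1, 1, , ])
  expect_equal(max(split), 2L)
  # >= 95 percent of nucleus pixels agree with the nearest-centroid oracle
  idx <- which(split[1, , ] > 0, arr.ind = TRUE)
  d1 <- (idx[, 1] - 1 - 20)^2 + (idx[, 2] - 1 - 24)^2
  d2 <- (idx[, 1] - 1 - 20)^2 + (idx[, 2] - 1 - 36)^2
  oracle <- ifelse(d1 <= d2, 1L, 2L)
  got <- split[1, , ][split[1, , ] > 0]
  # label identity is arbitrary; align by majority
  if (mean(got == oracle) < 0.5) oracle <- 3L - oracle
  expect_gte(mean(got == oracle), 0.95)
})

test_that("evaluate_segmentation scores greedy one-to-one matches", {
  truth <- cbind(c(10, 20, 30), c(10, 20, 30))
  perfect <- evaluate_segmentation(truth, truth, 1)
  expect_equal(perfect[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
  none <- evaluate_segmentation(truth[0, , drop = FALSE], truth, 1)
  expect_equal(none$recall, 0)
  # 2 matched + 1 false positive vs 3 truth -> P = R = 2/3
  pred <- cbind(c(10, 20, 90), c(10, 20, 90))
  pr <- evaluate_segmentation(pred, truth, 1)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
})
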