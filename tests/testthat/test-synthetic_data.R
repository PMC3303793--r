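# synthetic_data: photoconversion arithmetic, division conservation,
# rendering normalisation, determinism, and the dilution model itself.

mk_cells <- function(n = 3, x = c(50, 150, 250)) {
  photolineage:::new_cells(id = seq_len(n), y_um = rep(50, n), x_um = x,
                           radius_um = 2.5, converted_pool = 0,
                           unconverted_pool = 100, membrane_pool = 10)
}

test_that("apply_photoconversion moves pools and conserves the total", {
  cells <- mk_cells()
  stripe <- list(type = "stripe", x_min = 100, x_max = 200)

  full <- apply_photoconversion(cells, stripe, 1)
  expect_equal(full$converted_pool, c(0, 100, 0))
  expect_equal(full$unconverted_pool, c(100, 0, 100))

  none <- apply_photoconversion(cells, stripe, 0)
  expect_equal(none$converted_pool, cells$converted_pool)
  expect_equal(none$unconverted_pool, cells$unconverted_pool)

  part <- apply_photoconversion(cells, stripe, 0.95)
  expect_equal(part$converted_pool[2], 95)
  expect_equal(part$unconverted_pool[2], 5)
  # exact per-cell conservation, stripe and sphere regions alike
  expect_equal(part$converted_pool + part$unconverted_pool,
               cells$converted_pool + cells$unconverted_pool)
  sph <- apply_photoconversion(cells, list(type = "sphere",
                                           center = c(50, 150), radius = 5),
                               0.5)
  expect_equal(sph$converted_pool + sph$unconverted_pool,
               cells$converted_pool + cells$unconverted_pool)
  expect_error(apply_photoconversion(cells, stripe, 1.2), "p_conv")
})

test_that("advance_division conserves converted label and is reproducible", {
  parent <- mk_cells(1, x = 100)
  parent$converted_pool <- 80

  kids0 <- advance_division(parent, partition_cv = 0, steady_state = 100)
  expect_equal(kids0$converted_pool, c(40, 40))
  expect_equal(kids0$division_count, c(1L, 1L))
  expect_equal(kids0$parent, c(1L, 1L))
  expect_equal(kids0$unconverted_pool, c(100, 100))

  zero <- parent
  zero$converted_pool <- 0
  expect_equal(advance_division(zero, 0.3)$converted_pool, c(0, 0))

  # seeded draw as oracle: exact conservation and bit-reproducibility
  set.seed(11)
  kids1 <- advance_division(parent, partition_cv = 0.2, steady_state = 100)
  set.seed(11)
  kids2 <- advance_division(parent, partition_cv = 0.2, steady_state = 100)
  expect_identical(kids1$converted_pool, kids2$converted_pool)
  expect_equal(sum(kids1$converted_pool), parent$converted_pool)
  f <- kids1$converted_pool[1] / parent$converted_pool
  expect_true(f > 0 && f < 1)
  expect_error(advance_division(parent, partition_cv = -1), "partition_cv")
})

test_that("rendered integrated intensity is proportional to the pool", {
  sc <- photo_scenario("regeneration_7dpa", seed = 1, field_um = c(60, 60),
                       psf_sigma_um = 0,
                       noise = list(enabled = FALSE, offset = 0,
                                    quantize = FALSE))
  # zero pools, zero noise -> all-zero frame
  cells <- mk_cells(1, x = 30)
  cells$y_um <- 30
  cells$unconverted_pool <- 0
  cells$membrane_pool <- 0
  st0 <- render_frame(cells, sc)
  expect_true(all(st0$pixels == 0))

  # one cell, no noise, no blur: flux conservation within 1 percent
  cells$converted_pool <- 500
  st <- render_frame(cells, sc)
  integrated <- sum(st$pixels[1, 3, 1, , ])
  expect_lt(abs(integrated / (500 * 2 * pi * 2.5^2) - 1), 0.01)
})

test_that("membrane ridge lies on the nearest-centroid boundary", {
  sc <- photo_scenario("regeneration_7dpa", seed = 1, field_um = c(40, 60),
                       psf_sigma_um = 0,
                       noise = list(enabled = FALSE, offset = 0,
                                    quantize = FALSE))
  cells <- mk_cells(2, x = c(20, 37))  # bisector off the pixel grid
  cells$y_um <- c(20, 20)
  ridge <- photolineage:::membrane_ridges(cbind(cells$y_um, cells$x_um),
                                          cells$membrane_pool, 40, 60)
  got <- which(ridge > 0, arr.ind = TRUE)
  # brute-force oracle: a ridge pixel has a 4-neighbour closer to the other
  # centroid
  nearest <- function(y, x) {
    d <- (y - cells$y_um)^2 + (x - cells$x_um)^2
    which.min(d)
  }
  want <- matrix(FALSE, 40, 60)
  for (y in 1:40) for (x in 1:60) {
    me <- nearest(y - 1, x - 1)
    nb <- c(if (y > 1) nearest(y - 2, x - 1), if (y < 40) nearest(y, x - 1),
            if (x > 1) nearest(y - 1, x - 2), if (x < 60) nearest(y - 1, x))
    want[y, x] <- any(nb != me)
  }
  expect_identical(ridge > 0, want)
  # for two cells this is the perpendicular bisector: x = 28.5 band
  expect_true(all(abs(got[, 2] - 1 - 28.5) <= 1))
})

test_that("simulate_tissue is bit-deterministic given the seed", {
  sc <- small_regen_scenario(seed = 5, n_converted = 60, n_bystander = 20,
                             n_stump = 15)
  a <- simulate_tissue(sc)
  b <- simulate_tissue(sc)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("endpoint truth obeys the dilution model exactly", {
  sc <- small_regen_scenario(seed = 2)
  sim <- simulate_tissue(sc)
  tc <- sim$truth$cells
  conv <- tc[tc$converted & tc$division_count >= 0 &
               tc$x_um >= sc$plane_x_um, ]
  # pre-noise converted pool == p_conv * pool0_cell * 2^-d * partition product
  expect_equal(conv$converted_pool,
               sc$p_conv * conv$synth * 2^(-conv$division_count) *
                 conv$partition_product,
               tolerance = 1e-12)
  # monotonicity: more divisions => strictly lower mean converted pool
  m <- tapply(conv$converted_pool, conv$division_count, mean)
  expect_true(all(diff(m) < 0))
  # class proportions roughly as configured
  frac <- table(factor(conv$division_count, c(0, 2, 5))) / nrow(conv)
  expect_equal(as.numeric(frac), c(0.10, 0.30, 0.60), tolerance = 0.12)
})

test_that("timelapse truth: binary divisions, exact conservation, fixture", {
  sc <- photo_scenario("gastrulation_videoS1", seed = 3,
                       noise = list(enabled = FALSE))
  sim <- simulate_tissue(sc)
  lin <- sim$truth$lineage
  # every founder divides exactly once, with exactly 2 children
  expect_equal(sort(unique(lin$parent)), 1:3)
  expect_equal(as.numeric(table(lin$parent)), c(2, 2, 2))
  expect_equal(sort(unique(lin$frame)), c(2, 6))
  # conservation: daughters' pre-noise converted pools sum to the parent's
  cells <- sim$truth$cells
  for (p in unique(lin$parent)) {
    fr <- lin$frame[lin$parent == p][1]
    before <- cells$converted_pool[cells$frame == fr - 1 & cells$id == p]
    kids <- lin$child[lin$parent == p]
    after <- sum(cells$converted_pool[cells$frame == fr &
                                        cells$id %in% kids])
    expect_equal(after, before, tolerance = 1e-12)
  }
  # total converted pool across descendants equals founder pools thereafter
  tot <- tapply(cells$converted_pool[cells$converted_pool > 0],
                cells$frame[cells$converted_pool > 0], sum)
  expect_equal(as.numeric(tot), rep(tot[[1]], sc$n_frames),
               tolerance = 1e-12)
})

test_that("unknown presets and malformed scenarios are rejected", {
  expect_error(photo_scenario("lateral_line"), "arg")
  expect_error(photo_scenario("regeneration_7dpa", p_conv = 2), "p_conv")
  expect_error(photo_scenario("regeneration_7dpa",
                              class_proportions = c(0.5, 0.3, 0.1)),
               "sum to 1")
  expect_error(photo_scenario("regeneration_7dpa", bogus_field = 1),
               "unknown scenario fields")
})
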