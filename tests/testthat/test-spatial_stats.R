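# spatial_stats: principal axis, alignment / spacing statistics, rigid
# invariance and the permutation null.

test_that("principal_axis matches the closed-form 2x2 eigenvector", {
  on_x <- cbind(rep(0, 5), 1:5)        # (y, x): points along x
  expect_equal(principal_axis(on_x), c(0, 1))
  diag45 <- cbind(1:4, 1:4)
  expect_equal(principal_axis(diag45), c(1, 1) / sqrt(2))

  set.seed(5)
  pts <- cbind(rnorm(5), rnorm(5))
  ctr <- sweep(pts, 2, colMeans(pts))
  want <- oracle_eig2(crossprod(ctr))
  got <- principal_axis(pts)
  if (sum(got * want) < 0) want <- -want
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(principal_axis(cbind(c(1, 1), c(2, 2))), "distinct")
})

test_that("alignment and spacing statistics match direct formulas", {
  even <- cbind(rep(2, 6), seq(0, 25, by = 5))
  st <- alignment_and_spacing(even)
  expect_equal(st$alignment_rms, 0)
  expect_equal(st$spacing_cv, 0)

  # collinear with gaps {1, 3}: population sd / mean = 0.5
  gaps13 <- cbind(c(0, 0, 0), c(0, 1, 4))
  expect_equal(alignment_and_spacing(gaps13)$spacing_cv, 0.5)

  set.seed(6)
  pts <- cbind(runif(9, 0, 40), runif(9, 0, 40))
  ax <- principal_axis(pts)
  st2 <- alignment_and_spacing(pts, ax)
  ctr <- sweep(pts, 2, colMeans(pts))
  proj <- as.numeric(ctr %*% ax)
  perp <- ctr - outer(proj, ax)
  expect_equal(st2$alignment_rms, sqrt(mean(rowSums(perp^2))))
  g <- diff(sort(proj))
  expect_equal(st2$spacing_cv, sqrt(mean((g - mean(g))^2)) / mean(g))
  expect_error(alignment_and_spacing(pts[1:2, ]), "3 points")
  expect_error(alignment_and_spacing(cbind(c(0, 1, 2), c(5, 5, 5)),
                                     axis = c(0, 1)), "coincident")
})

test_that("statistics are invariant under rigid motions", {
  set.seed(61)
  pts <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  base <- alignment_and_spacing(pts, principal_axis(pts))
  for (theta in c(0.3, 1.2, 2.9)) {
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    moved <- sweep(pts %*% rot, 2, c(-13.7, 42.1), "+")
    got <- alignment_and_spacing(moved, principal_axis(moved))
    expect_equal(got$alignment_rms, base$alignment_rms, tolerance = 1e-9)
    expect_equal(got$spacing_cv, base$spacing_cv, tolerance = 1e-9)
  }
})

test_that("permutation_test: p-value definition, bounds and contract", {
  # perfectly ordered points: no null replicate can be as ordered
  pts <- cbind(rep(10, 8), seq(5, 40, by = 5))
  mask <- matrix(TRUE, 50, 50)
  res <- permutation_test(pts, mask, n_perm = 999, seed = 4)
  expect_equal(res$p_alignment, 1 / 1000)
  expect_equal(res$p_spacing, 1 / 1000)
  expect_gt(res$p_alignment, 0)  # add-one rule: never exactly 0

  res99 <- permutation_test(pts, mask, n_perm = 99, seed = 4)
  expect_equal(res99$n_perm, 99L)
  expect_error(permutation_test(pts, mask, n_perm = 50), "n_perm")
  expect_error(permutation_test(pts, matrix(FALSE, 5, 5), n_perm = 99),
               "empty")
})

test_that("permutation p-values are calibrated under the null", {
  # observed configurations drawn from the null itself: the empirical size
  # at nominal 0.05 must lie in [0.01, 0.12] over 200 repetitions
  mask <- matrix(TRUE, 40, 60)
  support <- which(mask)
  n <- 10
  hits_a <- 0L
  hits_s <- 0L
  set.seed(77)
  for (r in 1:200) {
    idx <- sample(support, n)
    pts <- cbind((idx - 1) %% 40 + runif(n), (idx - 1) %/% 40 + runif(n))
    res <- permutation_test(pts, mask, n_perm = 99, seed = 1000 + r)
    if (res$p_alignment < 0.05) hits_a <- hits_a + 1L
    if (res$p_spacing < 0.05) hits_s <- hits_s + 1L
  }
  expect_gte(hits_a / 200, 0.01)
  expect_lte(hits_a / 200, 0.12)
  expect_gte(hits_s / 200, 0.01)
  expect_lte(hits_s / 200, 0.12)
})

test_that("select_bright picks the top component or quantile", {
  rec <- data.frame(label = 1:4,
                    centroid_y_um = c(1, 2, 3, 4),
                    centroid_x_um = c(5, 6, 7, 8),
                    bgsub_mean_nuclear_converted = c(100, 95, 10, 12))
  m <- structure(list(K = 2L, weights = c(0.5, 0.5), means = c(100, 10),
                      sds = c(5, 5), constrained = FALSE),
                 class = "mixture_model")
  a <- assign_populations(m, rec)
  pts <- select_bright(a, rec)
  expect_equal(nrow(pts), 2L)
  expect_equal(pts[, "y"], c(1, 2))
  # brute-force posterior argmax oracle
  dens <- sapply(1:2, function(k)
    m$weights[k] * dnorm(rec$bgsub_mean_nuclear_converted, m$means[k],
                         m$sds[k]))
  expect_equal(which(max.col(dens) == 1L), which(a$component == 1L))

  q <- select_bright(a, rec, rule = "quantile:0.5")
  expect_equal(nrow(q), 2L)
  # empty selection errors with advice
  none <- a
  none$component[] <- 2L
  expect_error(select_bright(none, rec), "bright rule")
  expect_error(select_bright(a, rec, rule = "median"), "unknown")
})

test_that("guide-cell worlds reach the minimal permutation p-value", {
  # few enough guide cells that the line spacing stays resolvable
  sc <- small_regen_scenario(seed = 9, n_converted = 120, n_bystander = 40,
                             guide = list(enabled = TRUE, jitter_um = 0.01))
  sim <- simulate_tissue(sc)
  conv <- sim$stack$pixels[1, 3, 1, , ]
  keep <- (col(conv) - 1) >= sc$plane_x_um
  bg <- estimate_background(conv, exclude = !keep)
  work <- conv
  work[!keep] <- 0
  mask <- segment_nuclei(work, bg, 3, 20)
  rec <- measure_nuclei(mask, sim$stack, bg = list(nuclear_converted = bg))
  model <- fit_mixture(rec$bgsub_mean_nuclear_converted, 3, restarts = 5,
                       seed = 0)
  pts <- select_bright(assign_populations(model, rec), rec)
  res <- permutation_test(pts, keep, n_perm = 199, seed = 3)
  expect_equal(res$p_alignment, 1 / 200)
  expect_equal(res$p_spacing, 1 / 200)
})
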