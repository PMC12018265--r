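test_that("identical non-constant trials have consistency 1", {
  x <- matrix(rep(sin(seq_len(100) / 5), 6), 6, 100, byrow = TRUE)
  expect_equal(split_half_consistency(x, n_splits = 50, seed = 1), 1,
               tolerance = 1e-12)
})

test_that("independent white-noise trials have consistency near 0", {
  set.seed(7)
  x <- matrix(rnorm(20 * 150), 20, 150)
  expect_lt(abs(split_half_consistency(x, n_splits = 1000, seed = 2)), 0.1)
})

test_that("a fixed single split equals the direct two-group correlation", {
  set.seed(3)
  x <- matrix(rnorm(6 * 80), 6, 80)
  direct <- cor(colMeans(x[1:3, ]), colMeans(x[4:6, ]))
  est <- split_half_consistency(x, splits = list(1:3))
  expect_equal(est, direct, tolerance = 1e-12)
})

test_that("the split-half estimate is stable across seeds", {
  x <- simulate_band_trials(16, 300, structured = TRUE, snr = 2, seed = 4)
  v1 <- split_half_consistency(x, n_splits = 1000, seed = 10)
  v2 <- split_half_consistency(x, n_splits = 1000, seed = 20)
  expect_lt(abs(v1 - v2), 0.02)
  expect_identical(split_half_consistency(x, n_splits = 200, seed = 5),
                   split_half_consistency(x, n_splits = 200, seed = 5))
})

test_that("structured trials are more consistent than control trials", {
  d <- vapply(1:20, function(sd) {
    xs <- simulate_band_trials(12, 250, structured = TRUE, snr = 2,
                               pref = sd, seed = sd)
    xc <- simulate_band_trials(12, 250, structured = FALSE, seed = sd + 500)
    split_half_consistency(xs, 200, seed = sd) -
      split_half_consistency(xc, 200, seed = sd)
  }, numeric(1))
  expect_gt(mean(d), 0.3)
})

test_that("fewer than 4 trials is an error", {
  expect_error(split_half_consistency(matrix(rnorm(30), 3, 10)), "4 trials")
})

test_that("the block permutation test detects a clear shift", {
  set.seed(11)
  participant <- rep(1:5, each = 4)
  cons_b <- rnorm(20, 0, 0.05)
  res <- condition_difference_test(cons_b + 0.5, cons_b, participant,
                                   n_perm = 1000, seed = 1)
  expect_lte(res$p, 0.01)
  expect_gt(res$cohens_d, 1)
  expect_true(res$ci[1] <= res$statistic && res$statistic <= res$ci[2])
})

test_that("the permutation p never drops below its resolution", {
  set.seed(12)
  participant <- rep(1:5, each = 4)
  a <- rnorm(20) + 10
  res <- condition_difference_test(a, rnorm(20), participant,
                                   n_perm = 200, seed = 2)
  expect_equal(res$p, 1 / 201)
  expect_length(res$null, 200L)
})

test_that("equal conditions give an unremarkable p and tiny effect", {
  set.seed(13)
  participant <- rep(1:5, each = 4)
  x <- rnorm(20, 0, 0.1)
  res <- condition_difference_test(x, x + rnorm(20, 0, 0.1), participant,
                                   n_perm = 500, seed = 3,
                                   alternative = "two.sided")
  expect_gt(res$p, 0.05)
  expect_lt(abs(res$statistic), 0.1)
})

test_that("a single participant triggers the fallback warning", {
  expect_warning(
    condition_difference_test(rnorm(6), rnorm(6), rep(1, 6), n_perm = 100,
                              seed = 1),
    "single participant")
})

test_that("spatial correlation is exact for identical inputs", {
  set.seed(14)
  participant <- rep(1:5, each = 4)
  a <- rnorm(20)
  res <- cross_condition_spatial_correlation(a, a, participant,
                                             n_perm = 200, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p, 1 / 201)
})

test_that("independent consistency maps are not spatially correlated", {
  set.seed(15)
  participant <- rep(1:5, each = 4)
  res <- cross_condition_spatial_correlation(rnorm(20), rnorm(20),
                                             participant, n_perm = 500,
                                             seed = 4)
  expect_gt(res$p, 0.05)
})

test_that("small participant blocks are merged with a warning", {
  participant <- c(1, 1, 1, 2, 2, 2, 3, 3)
  expect_warning(
    cross_condition_spatial_correlation(rnorm(8), rnorm(8), participant,
                                        n_perm = 100, seed = 1),
    "merged")
})
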