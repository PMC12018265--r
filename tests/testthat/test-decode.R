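test_that("the task structure has its closed-form values", {
  st <- build_task_structure(c(0, 2, 4, 6), fs = 100)
  ## midpoint of a segment: phi = pi
  i_mid <- which.min(abs(st$t - 1))
  expect_equal(st$phi[i_mid], pi, tolerance = 1e-6)
  expect_equal(st$y_cos[i_mid], -1, tolerance = 1e-6)
  expect_equal(abs(st$y_nsin[i_mid]), 0, tolerance = 1e-6)
  ## 75% through a segment: -sin peaks (+1), the pre-turn peak
  i_75 <- which.min(abs(st$t - 1.5))
  expect_equal(st$y_nsin[i_75], 1, tolerance = 1e-6)
  ## at a turn the cosine peaks
  i_turn <- which.min(abs(st$t - 2))
  expect_equal(st$y_cos[i_turn], 1, tolerance = 1e-6)
  expect_true(all(abs(st$y_cos^2 + st$y_nsin^2 - 1) < 1e-12))
  expect_true(all(st$phi >= 0 & st$phi < 2 * pi))
  expect_error(build_task_structure(c(1), 100), "2 anchors")
})

test_that("phase recovery from components follows the resultant convention", {
  expect_equal(phase_from_components(1, 0), 0)
  expect_equal(phase_from_components(0, -1), pi / 2)
  expect_equal(phase_from_components(0, 1), 3 * pi / 2)
  expect_true(is.na(phase_from_components(0, 0)))
})

test_that("the decoder matches a brute-force normal-equation solve", {
  set.seed(21)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- cbind(rnorm(200), rnorm(200))
  model <- fit_decoder(X, y, trial_id = rep(1:10, each = 20),
                       folds = 5, repeats = 1, seed = 1)
  A <- cbind(1, X)
  W_brute <- solve(t(A) %*% A, t(A) %*% y)
  expect_lt(max(abs(model$weights - W_brute)), 1e-8)
})

test_that("exact predictors give near-perfect held-out reconstruction", {
  st <- build_task_structure(c(0, 1.9, 4.2, 6.1, 8.3, 10), fs = 25)
  nt <- length(st$phi)
  n_tr <- 8
  X <- do.call(rbind, replicate(n_tr, cbind(st$y_cos, st$y_nsin,
                                            st$y_cos, st$y_nsin),
                                simplify = FALSE))
  ## duplicated channels make the design rank deficient by construction;
  ## the ridge fallback announces itself (once per fold) and still
  ## recovers the phase
  expect_warning(thetanav:::ols_solve(cbind(1, X[1:100, ]), X[1:100, 1:2]),
                 "ridge")
  model <- suppressWarnings(
    fit_decoder(X, st, rep(1:n_tr, each = nt), folds = 4, repeats = 2,
                seed = 2))
  rep_out <- decode_cv_report(model, st)
  expect_lt(rep_out$report$mean_abs_err_deg, 1e-4)
})

test_that("pure-noise predictors decode at chance (~90 deg)", {
  st <- build_task_structure(c(0, 1.9, 4.2, 6.1, 8.3, 10), fs = 25)
  nt <- length(st$phi)
  n_tr <- 12
  set.seed(22)
  X <- matrix(rnorm(nt * n_tr * 18), nt * n_tr, 18)
  model <- fit_decoder(X, st, rep(1:n_tr, each = nt), folds = 6,
                       repeats = 2, seed = 3)
  rep_out <- decode_cv_report(model, st)
  expect_gt(rep_out$report$mean_abs_err_deg, 50)
  expect_lt(rep_out$report$mean_abs_err_deg, 130)
})

test_that("fold hygiene: every trial is scored from folds excluding it", {
  set.seed(23)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- cbind(rnorm(60), rnorm(60))
  model <- fit_decoder(X, y, rep(1:6, each = 10), folds = 3, repeats = 4,
                       seed = 4)
  expect_equal(dim(model$fold_id), c(6L, 4L))
  for (r in seq_len(4)) {
    expect_setequal(unique(model$fold_id[, r]), 1:3)
    expect_equal(as.vector(table(model$fold_id[, r])), rep(2L, 3))
  }
})

test_that("reconstruction reports behave at the three corner cases", {
  st <- build_task_structure(c(0, 2.2, 3.9, 6.4, 8.1, 10), fs = 50)
  phi <- st$phi
  ## perfect
  r0 <- reconstruction_report(phi, phi)
  expect_equal(r0$mean_abs_err_deg, 0, tolerance = 1e-9)
  expect_equal(sum(diag(r0$density) > 0), nrow(r0$density))
  expect_equal(mean(r0$density), 1, tolerance = 1e-9)
  expect_equal(sum(r0$hist$prop), 1, tolerance = 1e-12)
  ## constant 90 deg offset
  r90 <- reconstruction_report(wrap_phase(phi + pi / 2), phi)
  expect_equal(r90$circ_mean_deg, 90, tolerance = 1)
  ## independent uniform estimate: flat density
  set.seed(24)
  ru <- reconstruction_report(runif(20000, 0, 2 * pi),
                              runif(20000, 0, 2 * pi), n_bins = 10)
  expect_lt(max(abs(ru$density - 1)), 0.35)
  expect_lt(ru$resultant, 0.05)
  expect_true(all(ru$errors > -pi & ru$errors <= pi))
  expect_error(reconstruction_report(phi, phi, n_bins = 3), "n_bins")
})

test_that("the circular-shift null is exact for perfect reconstruction", {
  st <- build_task_structure(c(0, 1.7, 4.4, 5.9, 8.6, 10), fs = 50)
  res <- circular_shift_null(st$phi, st$phi, n_shifts = 500, seed = 5)
  expect_equal(res$statistic, 1)
  expect_equal(res$p, 1 / 501)
  set.seed(25)
  ind <- circular_shift_null(runif(length(st$phi), 0, 2 * pi), st$phi,
                             n_shifts = 500, seed = 6)
  expect_gt(ind$p, 0.05)
  expect_error(circular_shift_null(1:5, 1:5), "10 samples")
})

test_that("the route cross-correlogram of the structure peaks periodically", {
  seg <- 80
  n_seg <- 5
  y <- -sin(2 * pi * (seq_len(seg * n_seg) - 1) / seg)
  ccg <- crosscorrelogram_route(y, y, seg)
  expect_equal(ccg$r[ccg$lag_seg == 0], 1, tolerance = 1e-9)
  expect_equal(ccg$r[ccg$lag_seg == 1], 1, tolerance = 1e-9)
  expect_equal(ccg$r[ccg$lag_seg == -1], 1, tolerance = 1e-9)
  set.seed(26)
  noise <- rnorm(seg * n_seg)
  ccn <- crosscorrelogram_route(noise, y, seg)
  expect_lt(max(abs(ccn$r)), 0.25)
})

test_that("undistorted imagined trials reduce to real-trial decoding", {
  st <- build_task_structure(c(0, 2.1, 3.8, 6.2, 8.4, 10), fs = 25)
  nt <- length(st$phi)
  n_tr <- 8
  set.seed(27)
  mk <- function() {
    arr <- array(0, dim = c(n_tr, nt, 4))
    for (tr in seq_len(n_tr)) {
      arr[tr, , ] <- cbind(st$y_cos, st$y_nsin, st$y_cos, st$y_nsin) +
        matrix(rnorm(nt * 4, 0, 0.2), nt, 4)
    }
    arr
  }
  X <- matrix(aperm(mk(), c(2, 1, 3)), nt * n_tr, 4)
  model <- fit_decoder(X, st, rep(1:n_tr, each = nt), folds = 4,
                       repeats = 2, seed = 7)
  tset <- structure(list(series = mk(), time = st$t, anchors = st$anchors,
                         fs = 25, condition = "imagined"),
                    class = "trial_set")
  res <- decode_imagined(model, tset, st, participant = c(1, 1, 2, 2),
                         cap_s = 2, folds = 4, repeats = 2, seed = 8)
  expect_lt(res$report$mean_abs_err_deg, 15)
  expect_false(res$edge_flag)
})

test_that("reconstruction error grows monotonically with noise", {
  st <- build_task_structure(c(0, 2.1, 3.8, 6.2, 8.4, 10), fs = 20)
  nt <- length(st$phi)
  n_tr <- 8
  sds <- c(0, 0.5, 1, 2, 4)
  errs <- sapply(sds, function(s) {
    mean(vapply(1:10, function(seed) {
      set.seed(seed * 100 + round(s * 10))
      X <- do.call(rbind, replicate(n_tr,
        cbind(st$y_cos, st$y_nsin, st$y_cos, st$y_nsin) +
          matrix(rnorm(nt * 4, 0, s), nt, 4), simplify = FALSE))
      ## the zero-noise level is rank deficient (duplicated channels)
      model <- suppressWarnings(
        fit_decoder(X, st, rep(1:n_tr, each = nt), folds = 4,
                    repeats = 1, seed = seed))
      decode_cv_report(model, st)$report$mean_abs_err_deg
    }, numeric(1)))
  })
  expect_true(all(diff(errs) > -2))   # non-decreasing up to MC noise
  expect_lt(errs[1], 1)
  expect_gt(errs[5], 30)
})
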