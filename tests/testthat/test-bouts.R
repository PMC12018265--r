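## A hand-built tf_amplitude for contract-level detector checks.
toy_tf <- function(amp_series, freq = 8, fs = 50) {
  structure(list(amp = array(amp_series, dim = c(1, 1, length(amp_series))),
                 freqs = freq, fs = fs, zscored = FALSE),
            class = "tf_amplitude")
}
toy_bg <- function(freq = 8, thr_power = 1) {
  structure(list(slope = 0, intercept = 0,
                 threshold = matrix(thr_power, 1, 1), freqs = freq,
                 ci = 0.95),
            class = "background_fit")
}

test_that("background fit recovers a power-law slope and flat white noise", {
  freqs <- morse_freq_grid(c(1, 30), 10)
  set.seed(1)
  ## chi-squared(2)-type fluctuations around the power-law mean
  mp <- outer(c(1, 2), freqs^-1.5) * matrix(rgamma(2 * length(freqs), 40, 40),
                                            2)
  bg <- fit_background(mp, freqs, n_seconds = 100)
  expect_true(all(abs(bg$slope + 1.5) < 0.2))
  flat <- matrix(rgamma(length(freqs), 40, 40), 1)
  expect_lt(abs(fit_background(flat, freqs, n_seconds = 100)$slope), 0.2)
  fitted_mean <- exp(outer(bg$intercept, rep(1, length(freqs))) +
                     outer(bg$slope, log(freqs)))
  expect_true(all(bg$threshold > fitted_mean))
  expect_error(fit_background(flat, freqs, n_seconds = 5), "insufficient")
})

test_that("an oscillatory peak barely moves the robust background fit", {
  freqs <- morse_freq_grid(c(1, 30), 10)
  set.seed(2)
  base <- freqs^-1.5 * rgamma(length(freqs), 60, 60)
  peaked <- base * (1 + 3 * exp(-0.5 * ((log(freqs) - log(8)) / 0.1)^2))
  s_ex <- fit_background(matrix(peaked, 1), freqs, n_seconds = 100,
                         exclude_f = c(6, 10))$slope
  s_in <- fit_background(matrix(peaked, 1), freqs, n_seconds = 100)$slope
  expect_lt(abs(s_ex - s_in), 0.1)
})

test_that("runs shorter than two cycles are rejected", {
  fs <- 50
  f <- 8
  min_len <- ceiling(2 / f * fs)          # 13 samples
  a <- rep(0.1, 200)
  a[50:(50 + min_len - 3)] <- 2           # ~1.5 cycles
  bs <- detect_bouts(toy_tf(a, f, fs), toy_bg(f), c(7, 9),
                     wavelet_tb = NULL)
  expect_equal(nrow(bs$episodes), 0L)
  a[100:(100 + min_len + 3)] <- 2         # > 2 cycles
  bs2 <- detect_bouts(toy_tf(a, f, fs), toy_bg(f), c(7, 9),
                      wavelet_tb = NULL)
  expect_equal(nrow(bs2$episodes), 1L)
  expect_gte(min(bs2$episodes$stop_s - bs2$episodes$start_s), 2 / f)
})

test_that("masked samples break bout runs", {
  fs <- 50
  a <- rep(0.1, 200)
  a[50:100] <- 2
  mask <- rep(FALSE, 200)
  mask[70:72] <- TRUE
  bs <- detect_bouts(toy_tf(a, 8, fs), toy_bg(8), c(7, 9), mask = mask,
                     wavelet_tb = NULL)
  expect_equal(nrow(bs$episodes), 2L)
})

test_that("an injected strong bout is recovered with >= 80% overlap", {
  fs <- 250
  iv <- matrix(c(30, 30.5), 1)
  x <- simulate_bout_signal(60, fs, iv, freq = 8, snr = 6, seed = 3)
  tf <- morse_tf_amplitude(x, fs, c(1, 30), fs_out = 50, beta = 12)
  bg <- fit_background(matrix(rowMeans(tf$amp[1, , ]^2), 1), tf$freqs,
                       n_seconds = 60, exclude_f = c(5, 11))
  bs <- detect_bouts(tf, bg, c(6, 10))
  ov <- sum(pmax(0, pmin(bs$intervals$stop_s, 30.5) -
                    pmax(bs$intervals$start_s, 30)))
  expect_gte(ov / 0.5, 0.8)
})

test_that("prevalence equals an independent per-bin coverage computation", {
  fs <- 250
  iv <- matrix(c(10, 10.5, 25, 25.6, 40, 40.4), ncol = 2, byrow = TRUE)
  x <- simulate_bout_signal(60, fs, iv, freq = 7, snr = 4, seed = 8)
  tf <- morse_tf_amplitude(x, fs, c(1, 30), fs_out = 50, beta = 12)
  bg <- fit_background(matrix(rowMeans(tf$amp[1, , ]^2), 1), tf$freqs,
                       n_seconds = 60, exclude_f = c(4.5, 11))
  bs <- detect_bouts(tf, bg, c(5, 9))
  n_bins <- sum(tf$freqs >= 5 & tf$freqs <= 9)
  ep <- bs$episodes
  direct <- 100 * sum(ep$stop_s - ep$start_s) /
    (n_bins * bs$n_samples / bs$fs)
  expect_equal(bs$prevalence[1], direct, tolerance = 1e-9)
})

test_that("bout rate timecourse hits its extremes", {
  ind <- array(0, dim = c(5, 20, 2))
  ind[, 10, 1] <- 1
  rt <- bout_rate_timecourse(ind)
  expect_equal(rt[1, 10], 100)
  expect_equal(max(rt[2, ]), 0)
  expect_true(all(rt >= 0 & rt <= 100))
})

test_that("pre-turn prevalence matches full and empty coverage", {
  trials <- data.frame(start_s = c(0, 20))
  turns <- list(c(5, 10), c(25, 30))
  full <- data.frame(channel = 1,
                     start_s = c(3, 8, 23, 28), stop_s = c(5, 10, 25, 30))
  expect_equal(preturn_prevalence(full, trials, turns, 2, n_channels = 1), 1)
  none <- data.frame(channel = 1, start_s = 100, stop_s = 101)
  expect_equal(preturn_prevalence(none, trials, turns, 2, n_channels = 1), 0)
  expect_warning(
    preturn_prevalence(full, data.frame(start_s = 4.5), list(5), 2,
                       n_channels = 1),
    "clipped")
})
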