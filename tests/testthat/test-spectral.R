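make_tf <- function(seed = 1, n = 1500, n_ch = 2, f_range = c(3, 10)) {
  set.seed(seed)
  morse_tf_amplitude(matrix(rnorm(n * n_ch), n_ch, n, byrow = TRUE), 250,
                     f_range = f_range)
}

test_that("z-scoring gives exact zero mean and unit SD per (channel, freq)", {
  tf <- make_tf()
  z <- zscore_amplitude(tf, edge_s = 0)
  d <- dim(z$amp)
  for (cc in seq_len(d[1])) {
    mus <- apply(z$amp[cc, , ], 1, mean)
    sds <- apply(z$amp[cc, , ], 1, sd)
    expect_lt(max(abs(mus)), 1e-10)
    expect_lt(max(abs(sds - 1)), 1e-10)
  }
  expect_true(z$zscored)
  expect_error(zscore_amplitude(z), "already")
})

test_that("z-scoring is invariant to rescaling the raw amplitudes", {
  tf <- make_tf(2)
  tf2 <- tf
  tf2$amp <- 2 * tf2$amp
  z1 <- zscore_amplitude(tf, edge_s = 1)
  z2 <- zscore_amplitude(tf2, edge_s = 1)
  expect_equal(z1$amp, z2$amp, tolerance = 1e-10)
})

test_that("a constant channel cannot be z-scored", {
  tf <- make_tf(3)
  tf$amp[1, 1, ] <- 5
  expect_error(zscore_amplitude(tf, edge_s = 0), "variance")
})

test_that("masked samples are excluded from the statistics but transformed", {
  tf <- make_tf(4)
  nt <- dim(tf$amp)[3]
  mask <- rep(FALSE, nt)
  mask[1:200] <- TRUE
  z <- zscore_amplitude(tf, mask = mask, edge_s = 0)
  mus <- apply(z$amp[1, , !mask], 1, mean)
  expect_lt(max(abs(mus)), 1e-10)
  expect_equal(dim(z$amp)[3], nt)   # masked samples still present
})

test_that("the individualized band sits between neighbouring minima", {
  freqs <- morse_freq_grid(c(1, 30), 10)
  floor_1f <- freqs^-0.5
  bump <- function(f0, a, w) a * exp(-0.5 * ((log(freqs) - log(f0)) / w)^2)
  sp <- floor_1f + bump(2, 0.6, 0.15) + bump(8, 0.8, 0.15)
  b <- find_individual_band(sp, freqs)
  expect_equal(b$f_peak, freqs[which.min(abs(freqs - 8))], tolerance = 1e-9)
  expect_lt(b$f_lo, 8)
  expect_gt(b$f_hi, 8)
  expect_identical(b$band_name, "theta")

  ## two bumps in range: the taller one wins
  sp2 <- floor_1f + bump(4, 0.5, 0.15) + bump(8, 0.9, 0.15)
  b2 <- find_individual_band(sp2, freqs)
  expect_equal(b2$f_peak, freqs[which.min(abs(freqs - 8))], tolerance = 1e-9)

  expect_error(find_individual_band(freqs^-1, freqs), "local maximum")
})

test_that("band averaging reduces to the expected frequency means", {
  tf <- make_tf(5, f_range = c(3, 12))
  one <- band_average(tf, c(tf$freqs[4] - 1e-6, tf$freqs[4] + 1e-6))
  expect_equal(one, tf$amp[, 4, ])
  all_f <- band_average(tf, range(tf$freqs))
  expect_equal(all_f, apply(tf$amp, c(1, 3), mean))
  expect_error(band_average(tf, c(100, 200)), "no frequency bins")
  ## z-scored input: session mean of the band series is ~0
  z <- zscore_amplitude(tf, edge_s = 0)
  bz <- band_average(z, range(tf$freqs))
  expect_lt(max(abs(rowMeans(bz))), 1e-10)
})
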