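test_that("piecewise linear warping is exact on anchors and invertible", {
  fs <- 50
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 0.7 * t)
  a_src <- c(0, 3, 6.5, 10)
  a_dst <- c(0, 4, 6, 10)
  ## identity
  expect_equal(piecewise_linear_warp(x, fs, a_src, a_src), x,
               tolerance = 1e-12)
  ## uniform x2 stretch of a ramp halves the slope
  ramp <- t
  w <- piecewise_linear_warp(ramp, fs, c(0, 10), c(0, 20))
  tw <- seq(0, 20, by = 1 / fs)
  expect_equal(w, tw / 2, tolerance = 1e-9)
  ## round trip
  fwd <- piecewise_linear_warp(x, fs, a_src, a_dst)
  back <- piecewise_linear_warp(fwd, fs, a_dst, a_src)
  expect_lt(max(abs(back - x)), 0.02)
  expect_error(piecewise_linear_warp(x, fs, c(0, 5, 4, 10), a_dst),
               "increasing")
})

test_that("segment-length normalization makes the structure exactly periodic", {
  fs <- 50
  anchors <- c(0, 2.1, 4.9, 6.4, 9.2, 11)
  st <- build_task_structure(anchors, fs)
  norm <- normalize_segment_lengths(st$y_cos, fs, anchors)
  L <- attr(norm, "seg_len")
  expect_equal(length(norm), 5L * L)
  m <- matrix(norm, L)
  ## every segment carries the same cosine template
  expect_lt(max(abs(m - m[, 1])), 0.05)
  expect_error(normalize_segment_lengths(st$y_cos, fs, c(0, 0.001, 5)),
               "longer")
})

test_that("capped DTW recovers injected shifts and saturates at the cap", {
  fs <- 50
  anchors <- c(0, 2.3, 4.1, 6.6, 8.4, 10.6)
  phi <- build_task_structure(anchors, fs)$phi
  n <- length(phi)
  shift_by <- function(x, s_samp) {       # delay the series by s_samp
    c(rep(x[1], s_samp), x[seq_len(n - s_samp)])
  }
  ## aligned input -> identity path
  wp0 <- capped_dtw_align(phi, phi, fs, cap_s = 2)
  expect_lt(abs(wp0$mean_offset_s), 0.02)
  ## +1.5 s shift within the cap
  wp <- capped_dtw_align(shift_by(phi, 75), phi, fs, cap_s = 2)
  expect_lt(abs(wp$mean_offset_s - 1.5), 0.25)
  ## +3 s shift beyond the cap saturates
  wp3 <- capped_dtw_align(shift_by(phi, 150), phi, fs, cap_s = 2)
  expect_lte(max(abs(wp3$path[, 1] - wp3$path[, 2])) / fs, 2 + 1 / fs)
  expect_error(capped_dtw_align(phi, phi, fs, cap_s = 0.001), "one sample")
})

test_that("applying a warp path returns a series on the reference timeline", {
  fs <- 50
  anchors <- c(0, 2.3, 4.1, 6.6, 8.4, 10.6)
  phi <- build_task_structure(anchors, fs)$phi
  wp <- capped_dtw_align(phi, phi, fs, cap_s = 2)
  x <- sin(seq_len(length(phi)) / 20)
  y <- apply_warp_path(wp, x)
  expect_length(y, wp$ref_len)
  expect_lt(max(abs(y - x)), 1e-10)      # identity path
})

test_that("trajectory DTW finds identical anchors for identical trials", {
  rt <- route_template(4, "left", seed = 7)
  tr <- simulate_trajectory(rt, synth_config(), trial_seed = 3)
  al <- dtw_align_trajectories(list(tr, tr, tr), n_turns = 4)
  expect_equal(al$anchors[1, ], al$anchors[2, ], tolerance = 1e-9)
  ## single-trial turn localization is coarse; session-level recovery
  ## (averaging over trials) is checked separately at < 0.1 s
  gt <- trajectory_anchors(tr)
  expect_lt(mean(abs(al$anchors[1, ] - gt)), 0.3)
})

test_that("a uniformly slower trial maps anchors proportionally", {
  rt <- route_template(4, "left", seed = 7)
  tr <- simulate_trajectory(rt, synth_config(), trial_seed = 3, jitter = 0)
  n <- nrow(tr)
  idx <- seq(1, n, length.out = round(1.1 * n))
  tr2 <- data.frame(t = (seq_along(idx) - 1) / 120,
                    x = approx(seq_len(n), tr$x, idx)$y,
                    y = approx(seq_len(n), tr$y, idx)$y)
  attr(tr2, "turn_times") <- attr(tr, "turn_times") * 1.1
  attr(tr2, "fs") <- 120
  al <- dtw_align_trajectories(list(tr, tr, tr2), n_turns = 4)
  a1 <- al$anchors[1, 2:5]
  a2 <- al$anchors[3, 2:5]
  expect_lt(max(abs(a2 - 1.1 * a1)), 0.15)
})

test_that("short trials are dropped with a warning", {
  rt <- route_template(4, "left", seed = 7)
  tr <- simulate_trajectory(rt, synth_config(), trial_seed = 3)
  stub <- tr[seq_len(40), ]
  attr(stub, "turn_times") <- numeric(0)
  attr(stub, "fs") <- 120
  expect_warning(al <- dtw_align_trajectories(list(tr, tr, stub),
                                              n_turns = 4),
                 "dropped")
  expect_equal(nrow(al$anchors), 2L)
})

test_that("warping preserves the mean of smooth series", {
  fs <- 50
  t <- seq(0, 10, by = 1 / fs)
  x <- 2 + sin(2 * pi * 0.3 * t)
  w <- piecewise_linear_warp(x, fs, c(0, 4, 10), c(0, 5, 10))
  expect_lt(abs(mean(w) - mean(x)) / mean(x), 0.05)
})
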