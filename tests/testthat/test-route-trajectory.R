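test_that("route templates have the right geometry and are deterministic", {
  rt <- route_template(4, "left", seed = 7)
  expect_equal(rt$n_segments, 5L)
  expect_equal(rt$n_turns, 4L)
  expect_equal(nrow(rt$vertices), 6L)
  expect_true(all(rt$segment_lengths > 0))

  rt6 <- route_template(5, "left", seed = 7)   # participant-style extra turn
  expect_equal(rt6$n_segments, 6L)

  expect_error(route_template(0, "left", seed = 7), "n_turns")
  expect_identical(route_template(4, "right", seed = 3),
                   route_template(4, "right", seed = 3))
})

test_that("a jitter-free trajectory lies on the polyline with zero RMSE", {
  rt <- route_template(4, "left", seed = 7)
  tr <- simulate_trajectory(rt, synth_config(), trial_seed = 5, jitter = 0)
  expect_lt(route_rmse(tr, rt), 1e-9)
  tr2 <- simulate_trajectory(rt, synth_config(), trial_seed = 5, jitter = 0)
  expect_identical(tr, tr2)
})

test_that("walkers decelerate near turns", {
  rt <- route_template(4, "left", seed = 7)
  cfg <- synth_config()
  at_turn <- overall <- numeric(0)
  for (sd in 1:40) {
    tr <- simulate_trajectory(rt, cfg, trial_seed = sd)
    tt <- attr(tr, "turn_times")
    idx <- vapply(tt, function(x) which.min(abs(tr$t - x)), integer(1))
    at_turn <- c(at_turn, mean(tr$speed[idx]))
    overall <- c(overall, mean(tr$speed))
  }
  expect_lt(mean(at_turn), mean(overall))
})

test_that("turn times are strictly increasing and inside the trial", {
  rt <- route_template(4, "left", seed = 2)
  for (sd in 1:5) {
    tr <- simulate_trajectory(rt, synth_config(), trial_seed = sd)
    tt <- attr(tr, "turn_times")
    expect_length(tt, 4L)
    expect_false(is.unsorted(tt, strictly = TRUE))
    expect_true(all(tt > 0 & tt < max(tr$t)))
    expect_true(all(tr$speed >= 0))
  }
})

test_that("route RMSE has its closed-form value for a lateral offset", {
  rt <- route_template(1, "left", seed = 11)
  ## points offset 0.5 m on the convex (outer) side of the single left turn,
  ## where the nearest polyline point is always on the point's own segment
  pts <- NULL
  for (s in seq_len(rt$n_segments)) {
    a <- rt$vertices[s, ]; b <- rt$vertices[s + 1, ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    nrm <- c(-u[2], u[1])          # left normal; the turn bends left
    frac <- seq(0.05, 0.95, by = 0.05)
    pts <- rbind(pts, t(sapply(frac, function(f) a + f * (b - a) - 0.5 * nrm)))
  }
  traj <- data.frame(x = pts[, 1], y = pts[, 2])
  expect_equal(route_rmse(traj, rt), 0.5, tolerance = 1e-6)
  expect_error(route_rmse(data.frame(x = numeric(), y = numeric()), rt),
               "empty")
})
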