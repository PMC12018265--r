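test_that("turn-aligned averaging centres events at lag zero", {
  fs <- 50
  x <- rep(0, fs * 60)
  events <- c(10, 20, 30, 40)
  for (ev in events) x[round(ev * fs) + 1] <- 1
  avg <- turn_aligned_average(x, events, fs, window_s = c(-2, 2))
  expect_equal(avg$lag_s[which.max(avg$mean)], 0)
  expect_equal(max(avg$mean), 1)
  expect_equal(avg$n_events, 4L)
  expect_error(turn_aligned_average(x, numeric(0), fs), "no events")
})

test_that("random events give a flat average", {
  set.seed(31)
  fs <- 50
  x <- 1 + abs(gauss <- cumsum(rnorm(fs * 600)) / 50)
  x <- 1 + abs(sin(seq_along(x) / 37)) + rnorm(length(x), 0, 0.1)
  events <- runif(200, 5, 595)
  avg <- turn_aligned_average(x, events, fs, window_s = c(-2, 2))
  expect_lt(max(avg$mean) / min(avg$mean), 1.5)
})

test_that("a strong common deflection forms one maximal cluster", {
  set.seed(32)
  maps <- matrix(rnorm(18 * 60, 0, 0.3), 18, 60)
  maps[, 25:35] <- maps[, 25:35] + 2
  res <- cluster_signflip_test(maps, n_perm = 500, seed = 1)
  expect_true(all(res$mask[25:35]))
  ## the deflected region forms the dominant significant cluster
  expect_lte(min(res$clusters$p), 0.05)
  expect_false(any(res$mask[1:15]))
})

test_that("with p_cluster = 1 the test reduces to the point-wise test", {
  set.seed(33)
  maps <- matrix(rnorm(10 * 40), 10, 40)
  res <- cluster_signflip_test(maps, n_perm = 300, p_cluster = 1, seed = 2)
  expect_equal(res$mask, res$primary_mask)
})

test_that("the sign-flip cluster test controls family-wise error", {
  set.seed(34)
  hits <- vapply(1:200, function(i) {
    maps <- matrix(rnorm(8 * 30), 8, 30)
    res <- cluster_signflip_test(maps, n_perm = 500, seed = i)
    any(res$mask)
  }, logical(1))
  expect_lte(mean(hits), 0.075)
})

test_that("a single-channel effect among 18 is usually not significant", {
  set.seed(35)
  maps <- matrix(rnorm(18 * 40, 0, 1), 18, 40)
  maps[1, 15:20] <- maps[1, 15:20] + 4
  res <- cluster_signflip_test(maps, n_perm = 400, seed = 3)
  expect_lt(sum(res$mask), 3)
})

test_that("time-frequency maps are clustered with 4-connectivity", {
  set.seed(36)
  maps <- array(rnorm(12 * 8 * 20, 0, 0.3), dim = c(12, 8, 20))
  maps[, 3:5, 8:12] <- maps[, 3:5, 8:12] + 2
  res <- cluster_signflip_test(maps, n_perm = 300, seed = 4)
  expect_true(all(res$mask[3:5, 8:12]))
  expect_equal(dim(res$mask), c(8L, 20L))
})

test_that("peak latency is detected when bouts lead turns", {
  set.seed(37)
  lag_s <- seq(-3, 1.5, by = 0.02)
  mk_maps <- function(centres) {
    t(vapply(centres, function(ct) {
      exp(-0.5 * ((lag_s - ct) / 0.3)^2) + rnorm(length(lag_s), 0, 0.05)
    }, numeric(length(lag_s))))
  }
  participant <- rep(1:5, length.out = 18)
  ## centred at the turn: no latency shift
  r0 <- peak_latency_test(mk_maps(rnorm(18, 0, 0.05)), lag_s, participant,
                          n_perm = 500, seed = 1)
  expect_gt(r0$test$p, 0.05)
  ## 0.9 s early
  r1 <- peak_latency_test(mk_maps(rnorm(18, -0.9, 0.1)), lag_s, participant,
                          n_perm = 500, seed = 2)
  expect_lt(r1$mean_latency_s, -0.5)
  expect_lt(r1$test$p, 0.05)
  ## mixed +/- 0.9: cancellation
  r2 <- peak_latency_test(mk_maps(rep(c(-0.9, 0.9), 9)), lag_s, participant,
                          n_perm = 500, seed = 3)
  expect_gt(r2$test$p, 0.05)
  ## flat channels dropped with a warning
  maps <- mk_maps(rnorm(18, 0, 0.05))
  maps[3, ] <- 1
  expect_warning(peak_latency_test(maps, lag_s, participant, n_perm = 100,
                                   seed = 4),
                 "flat")
})

test_that("the lag profile shows that amplitude leads a delayed behaviour", {
  fs <- 20
  nt <- 400
  n_tr <- 6
  set.seed(38)
  band <- array(0, dim = c(n_tr, nt, 2))
  beh <- matrix(0, n_tr, nt)
  lag <- round(0.5 * fs)
  for (tr in seq_len(n_tr)) {
    a <- gauss_smooth_test(rnorm(nt), fs)
    band[tr, , 1] <- a
    band[tr, , 2] <- a + rnorm(nt, 0, 0.1)
    beh[tr, ] <- c(rep(a[1], lag), a[seq_len(nt - lag)])  # delayed copy
  }
  res <- behavior_theta_analysis(band, list(speed = beh), fs,
                                 participant = c(1, 2), max_lag_s = 2,
                                 n_perm = 200, seed = 1)
  pk <- res$lag_s[which.max(res$xcorr[1, 1, ])]
  expect_equal(pk, -0.5, tolerance = 0.1)
})

test_that("only the truly coupled behavioural variable is significant", {
  fs <- 20
  nt <- 300
  n_tr <- 10
  hits_phase <- hits_speed <- logical(20)
  for (sd in 1:20) {
    set.seed(400 + sd)
    phi <- wrap_phase(2 * pi * 5 * (seq_len(nt) - 1) / nt)
    band <- array(0, dim = c(n_tr, nt, 6))
    phase_reg <- matrix(rep(-sin(phi), n_tr), n_tr, nt, byrow = TRUE)
    speed <- matrix(rnorm(n_tr * nt), n_tr, nt)
    for (tr in seq_len(n_tr)) {
      for (cc in 1:6) {
        band[tr, , cc] <- -sin(phi) + rnorm(nt, 0, 1)
      }
    }
    res <- behavior_theta_analysis(band,
                                   list(est_phase = phase_reg,
                                        speed = speed),
                                   fs, participant = rep(1:3, each = 2),
                                   max_lag_s = 0.5, n_perm = 200,
                                   seed = sd)
    hits_phase[sd] <- res$p["est_phase"] < 0.05
    hits_speed[sd] <- res$p["speed"] < 0.05
  }
  expect_gte(mean(hits_phase), 0.8)
  expect_lte(mean(hits_speed), 0.2)
})

test_that("constant behavioural variables are dropped with a warning", {
  band <- array(rnorm(4 * 50 * 2), dim = c(4, 50, 2))
  expect_warning(
    res <- behavior_theta_analysis(band,
                                   list(ok = matrix(rnorm(200), 4),
                                        flat = matrix(1, 4, 50)),
                                   fs = 10, participant = c(1, 2),
                                   n_perm = 50, seed = 1),
    "flat")
  expect_identical(res$dropped, "flat")
})
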