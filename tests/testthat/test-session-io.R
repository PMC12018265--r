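test_that("sessions are bit-identical for identical configs and seeds", {
  cfg <- mini_config()
  s1 <- simulate_session(cfg, seed = 9)
  s2 <- simulate_session(cfg, seed = 9)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_session(cfg, seed = 10)
  expect_false(identical(s1$signals, s3$signals))
})

test_that("ground-truth phase advances 0 to 2*pi within each segment", {
  s <- mini_session()
  for (tr in c(1L, 3L)) {
    ph <- true_phase(s, tr, participant = 1)
    dphi <- diff(ph$phi)
    ## increases except at wrap points (one reset per segment boundary)
    resets <- sum(dphi < -pi)
    expect_equal(resets, s$route$n_turns)
    expect_true(all(dphi[dphi > -pi] >= -1e-9))
    expect_true(all(ph$phi >= 0 & ph$phi < 2 * pi))
  }
  ## control trials carry no phase
  ctrl <- which(s$trials$condition == "control")[1]
  expect_true(all(is.na(true_phase(s, ctrl)$phi)))
})

test_that("imagined-trial anchors are distorted but capped at +/- 2 s", {
  s <- mini_session()
  im <- grep("^imag_", s$trials$condition)[1]
  a <- s$ground_truth$anchors[[im]]
  expect_true(is.matrix(a))
  base <- s$ground_truth$mean_anchors / max(s$ground_truth$mean_anchors) *
    s$trials$duration[im]
  for (p in seq_len(nrow(a))) {
    rel <- a[p, ] - s$trials$start_s[im]
    expect_false(is.unsorted(rel, strictly = TRUE))
    inner <- 2:(length(rel) - 1L)
    expect_true(all(abs(rel[inner] - base[inner]) <= 2 + 0.3))
  }
})

test_that("injected bout coverage stays near the configured target", {
  cfg <- synth_config(n_channels = 6, n_participants = 3, n_real = 6,
                      n_imag = 0, n_control = 0)
  cov <- vapply(1:20, function(sd) {
    s <- simulate_session(cfg, seed = 200 + sd)
    gt <- s$ground_truth$bouts
    tot <- sum(s$trials$duration) * cfg$n_channels
    sum(gt$stop_s - gt$start_s) / tot
  }, numeric(1))
  expect_lt(abs(mean(cov) - 0.21), 0.03)
})

test_that("a session without injected discharges is barely flagged", {
  cfg <- synth_config(n_channels = 6, n_participants = 3, n_real = 6,
                      n_imag = 0, n_control = 0, ied_rate = 0)
  s <- simulate_session(cfg, seed = 31)
  m <- detect_ied(s$signals, s$fs)
  expect_lt(m$ied_fraction, 1)
  expect_equal(nrow(s$ground_truth$ied), 0L)
})

test_that("without phase locking, real and control are indistinguishable", {
  ## bout_amp_snr = 0: no theta signal at all, so split-half consistency
  ## should not separate conditions
  rejections <- vapply(1:10, function(sd) {
    cfg <- synth_config(n_channels = 6, n_participants = 3, n_real = 8,
                        n_imag = 0, n_control = 8, bout_amp_snr = 0,
                        ied_rate = 0)
    s <- simulate_session(cfg, seed = 700 + sd)
    proc <- process_session(s, pipeline_config(
      f_range = c(1, 30), do_bouts = FALSE, do_artifacts = FALSE,
      n_spectrum_trials = 4))
    vals <- lapply(list(proc$real_set, proc$ctrl_set), function(set) {
      vapply(seq_len(dim(set$series)[3]), function(cc) {
        split_half_consistency(set$series[, , cc], n_splits = 200,
                               seed = sd * 10 + cc)
      }, numeric(1))
    })
    condition_difference_test(vals[[1]], vals[[2]], proc$participant,
                              n_perm = 500, seed = sd)$p <= 0.05
  }, logical(1))
  expect_lte(sum(rejections), 2)
})

test_that("sessions round-trip through the on-disk format", {
  s <- mini_session()
  dir <- tempfile("session")
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$signals, s$signals)
  expect_equal(s2$trials, s$trials, tolerance = 1e-12)
  expect_equal(s2$ground_truth$bouts, s$ground_truth$bouts,
               tolerance = 1e-9)
  expect_equal(s2$route$vertices, s$route$vertices, tolerance = 1e-9)
  expect_equal(attr(s2$trajectories[[2]], "turn_times"),
               attr(s$trajectories[[2]], "turn_times"), tolerance = 1e-9)
  ## schema validation names the offending row
  tr <- read.csv(file.path(dir, "trials.csv"))
  tr$stop_s[3] <- tr$start_s[3] - 1
  write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(read_session(dir), "row 3")
  unlink(dir, recursive = TRUE)
})

test_that("EDF signals round-trip through the importer", {
  ## build a two-channel EDF file from scratch
  fs <- 250
  rec_dur <- 1
  n_rec <- 4L
  t <- seq(0, n_rec * rec_dur - 1 / fs, by = 1 / fs)
  x <- rbind(100 * sin(2 * pi * 6 * t), 50 * cos(2 * pi * 2 * t))
  path <- tempfile(fileext = ".edf")
  con <- file(path, "wb")
  pad <- function(s, n) writeChar(formatC(s, width = -n), con, n,
                                  eos = NULL)
  ns <- 2L
  pad("0", 8); pad("synthetic", 80); pad("synthetic", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(as.character(256 * (1 + ns)), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad(as.character(rec_dur), 8)
  pad(as.character(ns), 4)
  for (l in c("ch1", "ch2")) pad(l, 16)
  for (i in 1:ns) pad("synth", 80)
  for (i in 1:ns) pad("uV", 8)
  for (v in c(-200, -200)) pad(as.character(v), 8)   # phys min
  for (v in c(200, 200)) pad(as.character(v), 8)     # phys max
  for (v in c(-32768, -32768)) pad(as.character(v), 8)
  for (v in c(32767, 32767)) pad(as.character(v), 8)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(as.character(fs * rec_dur), 8)
  for (i in 1:ns) pad("", 32)
  dig <- round((x + 200) / 400 * 65535 - 32768)
  for (r in seq_len(n_rec)) {
    for (ch in 1:ns) {
      idx <- (r - 1) * fs + seq_len(fs)
      writeBin(as.integer(dig[ch, idx]), con, size = 2, endian = "little")
    }
  }
  close(con)
  edf <- read_edf(path)
  expect_equal(edf$fs, fs)
  expect_equal(edf$labels, c("ch1", "ch2"))
  expect_equal(dim(edf$signals), c(2L, length(t)))
  ## quantization error bounded by one digital step (~0.006 uV)
  expect_lt(max(abs(edf$signals - x)), 0.01)
  unlink(path)
})

test_that("the file-based pipeline driver runs end to end", {
  s <- mini_session()
  sdir <- tempfile("session")
  odir <- tempfile("out")
  write_session(s, sdir)
  cfg_file <- tempfile(fileext = ".cfg")
  writeLines(c("n_splits = 200", "n_perm = 200", "n_shifts = 500",
               "n_spectrum_trials = 4", "f_hi = 30"), cfg_file)
  ## two-channel participant blocks are merged for the spatial permutation
  res <- suppressWarnings(run_pipeline(cfg_file, sdir, odir, seed = 3))
  expect_true(file.exists(file.path(odir, "consistency.csv")))
  expect_true(file.exists(file.path(odir, "log.json")))
  log <- jsonlite::read_json(file.path(odir, "log.json"))
  expect_true(is.numeric(log$real_mean_abs_err_deg))
  ## determinism: rerunning with the same seed reproduces the outputs
  odir2 <- tempfile("out2")
  suppressWarnings(run_pipeline(cfg_file, sdir, odir2, seed = 3))
  expect_identical(readLines(file.path(odir, "consistency.csv")),
                   readLines(file.path(odir2, "consistency.csv")))
  unlink(c(sdir, odir, odir2), recursive = TRUE)
})
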