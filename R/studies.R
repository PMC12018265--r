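#' End-to-end decoding study on one session
#'
#' Runs the full decoding analysis: preprocessing ([process_session()]),
#' pooled-channel decoder fit with trial-wise cross-validation on the real
#' condition, a shuffled-structure control fit (per-trial circular shifts of
#' the responses), imagined- and control-condition decoding with
#' cross-validated capped-DTW alignment, circular-shift nulls, and the
#' segment-normalized cross-correlogram of the reconstructed -sine
#' component with the route structure.
#'
#' @param session a `session_bundle`.
#' @param config a [pipeline_config()].
#' @param seed integer seed for fold assignment and nulls.
#' @param proc optional precomputed [process_session()] result.
#' @param do_shuffled,do_ccg,do_imag_null stage toggles for the
#'   shuffled-structure control fit, the cross-correlogram and the
#'   imagined-condition shift null (all on by default; replicate studies
#'   that only score generalization can switch them off).
#' @return list with `model`, `real` (cv report), `shuffled` (cv report on
#'   shuffled structure), `imag`, `ctrl` ([decode_imagined()] results),
#'   `imag_null`, `ctrl_null` (circular-shift `permutation_result`s),
#'   `ccg_real` (cross-correlogram data frame), `seg_len`, `proc`.
#' @export
decode_study <- function(session, config = pipeline_config(f_range = c(1, 30)),
                         seed = 1L, proc = NULL, do_shuffled = TRUE,
                         do_ccg = TRUE, do_imag_null = TRUE) {
  if (is.null(proc)) proc <- process_session(session, config)
  st <- proc$structure
  nt <- length(st$phi)
  arr <- proc$real_set$series
  n_tr <- dim(arr)[1]
  n_ch <- dim(arr)[3]
  X <- matrix(aperm(arr, c(2, 1, 3)), nt * n_tr, n_ch)
  trial_id <- rep(seq_len(n_tr), each = nt)

  model <- fit_decoder(X, st, trial_id, folds = config$folds,
                       repeats = config$repeats, seed = seed)
  real <- decode_cv_report(model, st)

  ## Shuffled-structure control: per-trial circular shifts of the
  ## responses. A single shuffle leaves a residual common rotation (the
  ## resultant of n_tr random rotations), so each repeat draws fresh
  ## shifts and the held-out errors are pooled across repeats.
  shuffled <- NULL
  if (do_shuffled) {
    phi_shuf <- phi_ref <- NULL
    for (r in seq_len(config$repeats)) {
      y <- with_seed(derive_seed(seed, 100L + r), {
        do.call(rbind, lapply(seq_len(n_tr), function(tr) {
          s <- sample.int(nt, 1L)
          idx <- ((seq_len(nt) - 1L + s) %% nt) + 1L
          cbind(st$y_cos[idx], st$y_nsin[idx])
        }))
      })
      m_r <- fit_decoder(X, y, trial_id, folds = config$folds,
                         repeats = 1L, seed = derive_seed(seed, 200L + r))
      comp <- cbind(rowMeans(matrix(m_r$cv_pred[, 1], nt, n_tr)),
                    rowMeans(matrix(m_r$cv_pred[, 2], nt, n_tr)))
      phi_shuf <- c(phi_shuf, phase_from_components(comp[, 1], comp[, 2]))
      phi_ref <- c(phi_ref, st$phi)
    }
    shuffled <- reconstruction_report(phi_shuf, phi_ref)
  }

  imag <- ctrl <- imag_null <- ctrl_null <- NULL
  if (!is.null(proc$imag_set)) {
    imag <- decode_imagined(model, proc$imag_set, st, proc$participant,
                            cap_s = config$cap_s, folds = config$folds,
                            repeats = config$repeats,
                            seed = derive_seed(seed, 3L))
    if (do_imag_null) {
      imag_null <- circular_shift_null(imag$phi_hat_mean, st$phi,
                                       n_shifts = config$n_shifts,
                                       seed = derive_seed(seed, 4L))
    }
  }
  if (!is.null(proc$ctrl_set)) {
    ctrl <- decode_imagined(model, proc$ctrl_set, st, proc$participant,
                            cap_s = config$cap_s, folds = config$folds,
                            repeats = config$repeats,
                            seed = derive_seed(seed, 5L))
    ctrl_null <- circular_shift_null(ctrl$phi_hat_mean, st$phi,
                                     n_shifts = config$n_shifts,
                                     seed = derive_seed(seed, 6L))
  }

  ## segment-normalized cross-correlogram of the reconstructed -sine
  ccg_real <- seg_len <- NULL
  if (do_ccg) {
    anchors0 <- st$anchors - st$anchors[1]
    recon_nsin <- real$comp_mean[, 2]
    norm <- normalize_segment_lengths(
      recon_nsin, config$fs_decode,
      anchors0[anchors0 <= nt / config$fs_decode + 1e-9])
    seg_len <- attr(norm, "seg_len")
    y_per <- -sin(2 * pi * ((seq_along(norm) - 1L) %% seg_len) / seg_len)
    ccg_real <- crosscorrelogram_route(as.numeric(norm), y_per, seg_len,
                                       max_lag_segments = 2)
  }

  list(model = model, real = real$report, real_phi_hat = real$phi_hat,
       real_comp = real$comp_mean, shuffled = shuffled,
       imag = imag, ctrl = ctrl,
       imag_null = imag_null, ctrl_null = ctrl_null,
       ccg_real = ccg_real, seg_len = seg_len, structure = st, proc = proc)
}

#' Temporal-consistency study on one processed session
#'
#' Split-half consistency per channel and condition, condition contrasts
#' with the multilevel block permutation test (one-sided where the
#' hypotheses are directional: real > control, imagined > control) and the
#' spatial correlation of consistency between real and imagined conditions.
#'
#' @param proc a [process_session()] result.
#' @param n_splits split-half partitions (defaults to the pipeline config).
#' @param seed integer seed.
#' @return list with `consistency` (data frame: channel, participant,
#'   condition, value), `real_vs_ctrl`, `imag_vs_ctrl`
#'   (`permutation_result`s), `spatial` (spatial-correlation result).
#' @export
consistency_study <- function(proc, n_splits = proc$config$n_splits,
                              seed = 1L) {
  sets <- list(real = proc$real_set, imagined = proc$imag_set,
               control = proc$ctrl_set)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  participant <- proc$participant
  n_ch <- dim(proc$real_set$series)[3]
  cons <- do.call(rbind, lapply(names(sets), function(cond) {
    vals <- vapply(seq_len(n_ch), function(cc) {
      split_half_consistency(sets[[cond]]$series[, , cc],
                             n_splits = n_splits,
                             seed = derive_seed(seed, cc))
    }, numeric(1))
    data.frame(channel = seq_len(n_ch), participant = participant,
               condition = cond, value = vals)
  }))
  get <- function(cond) cons$value[cons$condition == cond]
  out <- list(consistency = cons)
  if (!is.null(sets$control)) {
    out$real_vs_ctrl <- condition_difference_test(
      get("real"), get("control"), participant,
      n_perm = proc$config$n_perm, seed = derive_seed(seed, 101L))
    if (!is.null(sets$imagined)) {
      out$imag_vs_ctrl <- condition_difference_test(
        get("imagined"), get("control"), participant,
        n_perm = proc$config$n_perm, seed = derive_seed(seed, 102L))
    }
  }
  if (!is.null(sets$imagined)) {
    out$spatial <- cross_condition_spatial_correlation(
      get("real"), get("imagined"), participant,
      n_perm = proc$config$n_perm, seed = derive_seed(seed, 103L))
  }
  out
}

#' Bout-detection study against synthetic ground truth
#'
#' Summarizes detector output per condition and scores it against the
#' generator's injected bout intervals: sensitivity (fraction of injected
#' bouts overlapped by a detection on the same channel), recovered
#' prevalence and duration, and the pre-turn prevalence in the real
#' condition.
#'
#' @param session the `session_bundle` (for ground truth).
#' @param proc the [process_session()] result.
#' @param window_s pre-turn window (s).
#' @return list with `sensitivity`, `prevalence` (Pepisode percent, mean
#'   over channels and band bins, per condition), `peak_prevalence`
#'   (Pepisode percent at each channel's theta-peak bin, mean over
#'   channels, per condition), `mean_duration` (s), `preturn` (per-channel
#'   pre-turn coverage), `rate_timecourse` (`channel x time` percent).
#' @export
bout_study <- function(session, proc, window_s = 2) {
  gt <- session$ground_truth$bouts
  det <- proc$bouts$intervals
  hit <- vapply(seq_len(nrow(gt)), function(i) {
    sub <- det[det$channel == gt$channel[i], , drop = FALSE]
    any(sub$start_s < gt$stop_s[i] & sub$stop_s > gt$start_s[i])
  }, logical(1))
  conds <- unique(sub("_(left|right)$", "", session$trials$condition))
  n_ch <- nrow(session$signals)
  f_peak <- vapply(seq_len(n_ch), function(cc) {
    proc$bands[[as.character(proc$participant[cc])]]$f_peak
  }, numeric(1))
  by_cond <- lapply(conds, function(cd) {
    ids <- grep(paste0("^", cd), session$trials$condition)
    b <- combine_bouts(proc$bouts_by_trial[ids])
    total_s <- sum(session$trials$duration[ids])
    ep <- b$episodes
    peak <- vapply(seq_len(n_ch), function(cc) {
      sub <- ep[ep$channel == cc &
                abs(log(ep$freq / f_peak[cc])) < log(2^(0.5 / 10)), ,
                drop = FALSE]
      100 * sum(sub$stop_s - sub$start_s) / total_s
    }, numeric(1))
    list(prevalence = mean(b$prevalence),
         peak_prevalence = mean(peak),
         duration = mean(b$mean_duration, na.rm = TRUE))
  })
  names(by_cond) <- conds

  turn_times <- lapply(seq_along(proc$real_trials), function(k) {
    i <- proc$real_trials[k]
    session$trials$start_s[i] +
      proc$anchors[k, 2:(ncol(proc$anchors) - 1L)]
  })
  preturn <- preturn_prevalence(proc$bouts,
                                session$trials[proc$real_trials, ],
                                turn_times, window_s = window_s,
                                n_channels = nrow(session$signals))
  list(sensitivity = mean(hit),
       prevalence = vapply(by_cond, `[[`, 0, "prevalence"),
       peak_prevalence = vapply(by_cond, `[[`, 0, "peak_prevalence"),
       mean_duration = vapply(by_cond, `[[`, 0, "duration"),
       preturn = preturn,
       rate_timecourse = bout_rate_timecourse(proc$bout_ind_real))
}

#' Bout-detector calibration on a single synthetic channel
#'
#' Injects sinusoidal bouts of known coverage and duration into a 1/f
#' background, runs the full detection chain (detection-wavelet transform,
#' background fit with the oscillatory band excluded, episode detection
#' with smearing correction) and scores sensitivity and the recovery of the
#' configured prevalence and duration at the bout frequency bin. With
#' `snr = 0` no bouts are injected and the run measures the false-positive
#' prevalence on pure background over a standard theta range.
#'
#' @param seed integer seed.
#' @param duration_s signal length (s).
#' @param fs sampling rate (Hz).
#' @param snr bout amplitude in background-SD units (0 = noise only).
#' @param coverage target fraction of time covered by bouts.
#' @param dur_mean,dur_sd bout duration distribution (s).
#' @param freq bout frequency (Hz).
#' @param tb detection-wavelet time-bandwidth product.
#' @param noise_band band used for the noise-only prevalence (Hz).
#' @return list with `sensitivity`, `prevalence` (Pepisode percent at the
#'   bout frequency bin, or the noise-band mean when `snr = 0`),
#'   `mean_duration` (s), `injected_prevalence` (percent),
#'   `n_injected`.
#' @export
bout_calibration <- function(seed, duration_s = 240, fs = 250, snr = 3,
                             coverage = 0.21, dur_mean = 0.52,
                             dur_sd = 0.08, freq = 6.5, tb = 36,
                             noise_band = c(4, 9)) {
  iv <- NULL
  if (snr > 0) {
    iv <- with_seed(seed, {
      n_b <- round(coverage * duration_s / dur_mean)
      out <- matrix(numeric(), 0, 2)
      for (b in seq_len(n_b)) {
        for (att in seq_len(60L)) {
          d <- max(2 / freq + 0.02, rnorm(1, dur_mean, dur_sd))
          s0 <- runif(1, 0, duration_s - d)
          if (nrow(out) == 0L ||
              all(s0 >= out[, 2] + 0.15 | s0 + d <= out[, 1] - 0.15)) {
            out <- rbind(out, c(s0, s0 + d))
            break
          }
        }
      }
      out
    })
  }
  x <- simulate_bout_signal(duration_s, fs, iv, freq = freq, snr = snr,
                            seed = derive_seed(seed, 1L))
  tf <- morse_tf_amplitude(x, fs, f_range = c(1, 30), fs_out = 50,
                           beta = tb / 3)
  mp <- matrix(rowMeans(tf$amp[1, , ]^2), 1)
  if (snr > 0) {
    bg <- fit_background(mp, tf$freqs, n_seconds = duration_s,
                         exclude_f = c(freq / 1.6, freq * 1.6))
    k <- which.min(abs(tf$freqs - freq))
    bs <- detect_bouts(tf, bg, tf$freqs[k] * c(0.999, 1.001),
                       wavelet_tb = tb)
    hit <- vapply(seq_len(nrow(iv)), function(i) {
      any(bs$episodes$start_s < iv[i, 2] & bs$episodes$stop_s > iv[i, 1])
    }, logical(1))
    list(sensitivity = mean(hit), prevalence = bs$prevalence,
         mean_duration = bs$mean_duration,
         injected_prevalence = 100 * sum(iv[, 2] - iv[, 1]) / duration_s,
         injected_duration = mean(iv[, 2] - iv[, 1]),
         n_injected = nrow(iv))
  } else {
    bg <- fit_background(mp, tf$freqs, n_seconds = duration_s)
    bs <- detect_bouts(tf, bg, noise_band, wavelet_tb = tb)
    list(sensitivity = NA_real_, prevalence = bs$prevalence,
         mean_duration = bs$mean_duration, injected_prevalence = 0,
         injected_duration = NA_real_, n_injected = 0L)
  }
}

#' IED-detection study against synthetic ground truth
#'
#' @param session the `session_bundle`.
#' @param mask a [detect_ied()] result for the session.
#' @param extend_s guard extension applied to the injected intervals when
#'   computing their coverage, matching the detector's contract of flagging
#'   the up-/down-ramping 256 ms around each discharge.
#' @return list with `all_detected` (every injected discharge overlapped by
#'   a flagged interval), `flagged_pct`, `injected_pct` (percent of samples
#'   inside guard-extended injected intervals), `injected_raw_pct` (without
#'   the guard), `n_injected`.
#' @export
ied_study <- function(session, mask, extend_s = 0.256) {
  gt <- session$ground_truth$ied
  n <- ncol(session$signals)
  fs <- session$fs
  inj <- rep(FALSE, n)
  inj_g <- rep(FALSE, n)
  hit <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    idx <- sample_range(gt$start_s[i], gt$stop_s[i], fs, n)
    inj[idx] <- TRUE
    inj_g[sample_range(gt$start_s[i] - extend_s, gt$stop_s[i] + extend_s,
                       fs, n)] <- TRUE
    hit[i] <- any(mask$mask[idx])
  }
  list(all_detected = all(hit), flagged_pct = mask$ied_fraction,
       injected_pct = 100 * mean(inj_g),
       injected_raw_pct = 100 * mean(inj), n_injected = nrow(gt))
}

#' Turn-locked group statistics on one processed session
#'
#' Turn-aligned averages of the warped band series per channel, the
#' cluster-based sign-flip test of the across-channel mean, and the
#' peak-latency test against zero.
#'
#' @param proc a [process_session()] result.
#' @param window_s `c(before, after)` window around turns (s).
#' @param seed integer seed.
#' @return list with `lag_s`, `maps` (`channel x lag` turn-locked means),
#'   `cluster` (`cluster_test_result`), `latency` ([peak_latency_test()]
#'   output).
#' @export
turn_stats_study <- function(proc, window_s = c(-3, 1.5), seed = 1L) {
  fs <- proc$config$fs_decode
  arr <- proc$real_set$series
  n_ch <- dim(arr)[3]
  anchors0 <- proc$structure$anchors - proc$structure$anchors[1]
  turns <- anchors0[2:(length(anchors0) - 1L)]
  maps <- NULL
  for (cc in seq_len(n_ch)) {
    tavg <- turn_aligned_average(
      lapply(seq_len(dim(arr)[1]), function(tr) arr[tr, , cc]),
      rep(list(turns), dim(arr)[1]), fs, window_s = window_s)
    maps <- rbind(maps, tavg$mean)
  }
  lag_s <- seq(round(window_s[1] * fs), round(window_s[2] * fs)) / fs
  cluster <- cluster_signflip_test(maps, n_perm = proc$config$n_perm,
                                   p_primary = proc$config$p_primary,
                                   p_cluster = proc$config$p_cluster,
                                   seed = seed)
  latency <- peak_latency_test(maps, lag_s, proc$participant,
                               n_perm = proc$config$n_perm,
                               seed = derive_seed(seed, 1L))
  list(lag_s = lag_s, maps = maps, cluster = cluster, latency = latency)
}

#' Run the complete analysis pipeline on a session
#'
#' Convenience driver executing every stage in dependency order
#' (artifacts/spectra/bouts/warping via [process_session()], then
#' consistency, decoding and turn-locked statistics) and returning all
#' results in one list.
#'
#' @param session a `session_bundle`.
#' @param config a [pipeline_config()].
#' @param seed integer seed used for all stochastic stages.
#' @return list with `proc`, `decode`, `consistency`, `bouts`, `ied`,
#'   `turns`.
#' @export
run_navigation_pipeline <- function(session,
                                    config = pipeline_config(
                                      f_range = c(1, 30)),
                                    seed = 1L) {
  proc <- process_session(session, config)
  dec <- decode_study(session, config, seed = seed, proc = proc)
  cons <- consistency_study(proc, seed = derive_seed(seed, 11L))
  bts <- bout_study(session, proc)
  ied <- ied_study(session, proc$mask)
  trn <- turn_stats_study(proc, seed = derive_seed(seed, 12L))
  list(proc = proc, decode = dec, consistency = cons, bouts = bts,
       ied = ied, turns = trn)
}
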