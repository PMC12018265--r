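#' Analysis pipeline configuration
#'
#' Collects every analysis constant in one place. Defaults follow the
#' recording and analysis conventions the pipeline is built around: 250 Hz
#' signals band-limited to 1-90 Hz, Morse wavelets (gamma = 3, P^2 = 60)
#' with 10 voices per octave, IED rejection at 5x the median envelope with
#' 256 ms extension and a 50% trial-exclusion rule, bout detection at the
#' 0.95 background quantile for >= 2 cycles, 1000 split-half partitions,
#' 10 x 10 cross-validation, a +/- 2 s alignment cap, 10000 circular shifts
#' and 0.05 primary/cluster thresholds.
#'
#' @param f_range wavelet frequency range (Hz) used by the analyses. The
#'   full recording bandwidth is 1-90 Hz; desk-scale studies restrict to
#'   1-30 Hz since all bands of interest (delta, theta, beta) lie below
#'   30 Hz.
#' @param voices wavelet voices per octave.
#' @param theta_search theta-peak search range (Hz).
#' @param edge_s cone-of-influence margin excluded from normalization (s).
#' @param ied_thresh_mult,ied_extend_s,ied_exclude_frac IED detector
#'   constants.
#' @param bout_ci,bout_min_cycles bout detector constants.
#' @param bout_tb time-bandwidth product of the detection wavelet (36, the
#'   6-cycle convention of the BOSC detector family; the amplitude-dynamics
#'   wavelet keeps P^2 = 60).
#' @param n_splits split-half partitions.
#' @param folds,repeats cross-validation scheme.
#' @param cap_s DTW alignment cap (s).
#' @param n_shifts circular shifts for the reconstruction null.
#' @param n_perm permutations for block-permutation tests.
#' @param p_primary,p_cluster cluster-test thresholds.
#' @param fs_decode sampling rate (Hz) of the warped common timeline used
#'   for consistency and decoding (band envelopes are smooth, so 50 Hz
#'   retains them losslessly).
#' @param do_bouts stage toggle: run bout detection in
#'   [process_session()] (switch off for decoding-only studies).
#' @param do_artifacts stage toggle: run IED detection (switch off for
#'   focused studies on artifact-free synthetic data).
#' @param n_spectrum_trials number of real trials entering the session-mean
#'   spectra for band finding and background fitting (`Inf` = all; the
#'   spectra stabilize after a handful of trials).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(f_range = c(1, 90), voices = 10,
                            theta_search = c(3, 12), edge_s = 2,
                            ied_thresh_mult = 5, ied_extend_s = 0.256,
                            ied_exclude_frac = 0.5,
                            bout_ci = 0.95, bout_min_cycles = 2,
                            bout_tb = 36, n_splits = 1000L, folds = 10L, repeats = 10L,
                            cap_s = 2, n_shifts = 10000L, n_perm = 1000L,
                            p_primary = 0.05, p_cluster = 0.05,
                            fs_decode = 50, do_bouts = TRUE,
                            do_artifacts = TRUE,
                            n_spectrum_trials = Inf) {
  structure(list(f_range = f_range, voices = voices,
                 do_bouts = do_bouts, do_artifacts = do_artifacts,
                 n_spectrum_trials = n_spectrum_trials,
                 theta_search = theta_search, edge_s = edge_s,
                 ied_thresh_mult = ied_thresh_mult,
                 ied_extend_s = ied_extend_s,
                 ied_exclude_frac = ied_exclude_frac,
                 bout_ci = bout_ci, bout_min_cycles = bout_min_cycles,
                 bout_tb = bout_tb,
                 n_splits = n_splits, folds = folds, repeats = repeats,
                 cap_s = cap_s, n_shifts = n_shifts, n_perm = n_perm,
                 p_primary = p_primary, p_cluster = p_cluster,
                 fs_decode = fs_decode),
            class = "pipeline_config")
}

#' Preprocess a session: artifacts, spectra, bands, bouts, warped trials
#'
#' Runs the front half of the analysis pipeline on a session bundle:
#' 1. IED detection and masking on the continuous signals;
#' 2. per-trial Morse-wavelet amplitudes; session-mean amplitude and power
#'    spectra from artifact-free real-walk samples (outside the 2 s
#'    cone-of-influence margins);
#' 3. individualized theta band per participant (spectral peak in 3-12 Hz
#'    between neighbouring minima, on the participant-mean spectrum);
#' 4. 1/f background fit and bout detection per trial (raw power);
#' 5. session z-scoring of band amplitudes and per-channel band series;
#' 6. trajectory DTW to identify turn anchors of real trials, piecewise
#'    linear warping of real trials to the mean timing, linear warping of
#'    imagined/control trials to the same common timeline.
#'
#' @param session a `session_bundle`.
#' @param config a [pipeline_config()].
#' @return a list of class `processed_session` with elements `mask`,
#'   `spectra` (channel x frequency mean amplitude), `freqs`, `bands`
#'   (per-participant `band_definition`s), `background`, `bouts` (combined
#'   `bout_set`), `bouts_by_trial`, `real_set`, `imag_set`, `ctrl_set`
#'   (`trial_set`s on the common timeline), `bout_ind_real` (warped bout
#'   indicators), `structure` (`task_structure` on the common timeline),
#'   `anchors` (real-trial turn anchors, trial-relative seconds),
#'   `real_trials`, `imag_trials`, `ctrl_trials` (session trial indices),
#'   `config`.
#' @export
process_session <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "session_bundle"))
  fs <- session$fs
  N <- ncol(session$signals)
  trials <- session$trials
  n_ch <- nrow(session$signals)
  participant <- session$channels$participant

  if (isTRUE(config$do_artifacts)) {
    mask <- detect_ied(session$signals, fs, trials = trials,
                       thresh_mult = config$ied_thresh_mult,
                       extend_s = config$ied_extend_s,
                       exclude_frac = config$ied_exclude_frac)
  } else {
    mask <- structure(list(mask = rep(FALSE, N),
                           intervals = data.frame(channel = integer(),
                                                  start_s = numeric(),
                                                  stop_s = numeric()),
                           ied_fraction = 0, fs = fs,
                           trial_excluded = rep(FALSE, nrow(trials))),
                      class = "artifact_mask")
  }

  real_trials <- grep("^real_", trials$condition)
  imag_trials <- grep("^imag_", trials$condition)
  ctrl_trials <- which(trials$condition == "control")

  trial_idx <- lapply(seq_len(nrow(trials)), function(i) {
    sample_range(trials$start_s[i], trials$stop_s[i], fs, N)
  })

  ## ---- pass 1: full-range TF of real trials -> session spectra ---------
  freqs <- morse_freq_grid(config$f_range, config$voices)
  amp_sum <- matrix(0, n_ch, length(freqs))
  pow_sum <- matrix(0, n_ch, length(freqs))
  n_spec <- 0L
  fs_tf <- config$fs_decode
  edge <- round(config$edge_s * fs_tf)
  spec_trials <- real_trials
  if (is.finite(config$n_spectrum_trials) &&
      config$n_spectrum_trials < length(real_trials)) {
    spec_trials <- real_trials[round(seq(1, length(real_trials),
                                         length.out =
                                           config$n_spectrum_trials))]
  }
  pow_det_sum <- matrix(0, n_ch, length(freqs))
  beta_det <- config$bout_tb / 3
  for (i in spec_trials) {
    idx <- trial_idx[[i]]
    tf <- morse_tf_amplitude(session$signals[, idx, drop = FALSE], fs,
                             f_range = config$f_range,
                             voices = config$voices, fs_out = fs_tf)
    nt <- dim(tf$amp)[3]
    use <- rep(TRUE, nt)
    if (edge > 0 && nt > 2 * edge) {
      use[c(seq_len(edge), nt - seq_len(edge) + 1L)] <- FALSE
    }
    use <- use & !decimate_mask(mask$mask, idx, fs, fs_tf, nt)
    if (!any(use)) next
    a <- tf$amp[, , use, drop = FALSE]
    amp_sum <- amp_sum + rowSums(a, dims = 2L)
    pow_sum <- pow_sum + rowSums(a^2, dims = 2L)
    n_spec <- n_spec + sum(use)
    if (isTRUE(config$do_bouts)) {
      ## detection-wavelet power spectrum (shorter wavelet, wider bandwidth)
      tfd <- morse_tf_amplitude(session$signals[, idx, drop = FALSE], fs,
                                f_range = config$f_range,
                                voices = config$voices, fs_out = fs_tf,
                                beta = beta_det)
      pow_det_sum <- pow_det_sum +
        rowSums(tfd$amp[, , use, drop = FALSE]^2, dims = 2L)
    }
  }
  spectra <- amp_sum / n_spec
  mean_power <- pow_sum / n_spec

  ## ---- individualized bands per participant ----------------------------
  parts <- sort(unique(participant))
  bands <- lapply(parts, function(p) {
    sp <- colMeans(spectra[participant == p, , drop = FALSE])
    find_individual_band(sp, freqs, config$theta_search[1],
                         config$theta_search[2])
  })
  names(bands) <- parts
  band_lo <- min(vapply(bands, `[[`, 0, "f_lo"))
  band_hi <- max(vapply(bands, `[[`, 0, "f_hi"))

  background <- fit_background(
    if (isTRUE(config$do_bouts)) pow_det_sum / n_spec else mean_power,
    freqs, n_seconds = n_spec / fs_tf,
    exclude_f = c(band_lo, band_hi), ci = config$bout_ci)

  ## ---- pass 2: band-restricted TF for all trials ------------------------
  n_trials <- nrow(trials)
  tf_band <- vector("list", n_trials)
  mask_band <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    idx <- trial_idx[[i]]
    tf_band[[i]] <- morse_tf_amplitude(session$signals[, idx, drop = FALSE],
                                       fs, f_range = c(band_lo, band_hi),
                                       voices = config$voices,
                                       fs_out = fs_tf)
    mask_band[[i]] <- decimate_mask(mask$mask, idx, fs, fs_tf,
                                    dim(tf_band[[i]]$amp)[3])
  }

  ## bouts on raw detection-wavelet power, per trial
  bouts <- bouts_by_trial <- NULL
  if (isTRUE(config$do_bouts)) {
    bouts_by_trial <- lapply(seq_len(n_trials), function(i) {
      tfd <- morse_tf_amplitude(
        session$signals[, trial_idx[[i]], drop = FALSE], fs,
        f_range = c(band_lo, band_hi), voices = config$voices,
        fs_out = fs_tf, beta = beta_det)
      detect_bouts(tfd, background,
                   band = c(band_lo, band_hi), mask = mask_band[[i]],
                   t0 = trials$start_s[i],
                   min_cycles = config$bout_min_cycles,
                   wavelet_tb = config$bout_tb)
    })
    bouts <- combine_bouts(bouts_by_trial)
  }

  ## session z-scoring, then per-channel series over the participant band
  zstats <- tf_session_stats(tf_band, mask_band, edge_s = config$edge_s)
  series <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ztf <- zscore_amplitude(tf_band[[i]], stats = zstats)
    series[[i]] <- channel_band_series(ztf, bands, participant)
    tf_band[i] <- list(NULL)   # free; plain NULL assignment would shift ids
  }

  ## ---- warping to the common timeline -----------------------------------
  align <- dtw_align_trajectories(session$trajectories,
                                  n_turns = session$route$n_turns)
  anchors <- align$anchors
  mean_anchors <- colMeans(anchors)
  fs_out <- config$fs_decode
  real_set <- warp_trials(series[real_trials[align$kept]], anchors, fs_tf,
                          fs_out = fs_out, anchors_dst = mean_anchors,
                          condition = "real")

  ## warped bout indicators for the real condition
  bout_ind_real <- NULL
  if (isTRUE(config$do_bouts)) {
    ind_list <- lapply(real_trials[align$kept], function(i) {
      nt_i <- ncol(series[[i]])
      do.call(rbind, lapply(seq_len(n_ch), function(cc) {
        as.numeric(bout_indicator(bouts_by_trial[[i]], cc, nt_i, fs_tf,
                                  t0 = trials$start_s[i]))
      }))
    })
    bout_ind_real <- warp_trials(ind_list, anchors, fs_tf, fs_out = fs_out,
                                 anchors_dst = mean_anchors,
                                 condition = "real_bout_ind")
  }

  lin_warp_set <- function(ids, label) {
    if (length(ids) == 0L) return(NULL)
    a_src <- cbind(0, trials$duration[ids])
    warp_trials(series[ids], a_src, fs_tf, fs_out = fs_out,
                anchors_dst = c(0, mean_anchors[length(mean_anchors)]),
                condition = label)
  }
  imag_set <- lin_warp_set(imag_trials, "imagined")
  ctrl_set <- lin_warp_set(ctrl_trials, "control")

  structure_ts <- build_task_structure(mean_anchors, fs_out)
  ## warp_trials and build_task_structure share the anchor grid, but the
  ## final sample can differ by one due to rounding; trim to the shorter
  nt_common <- min(dim(real_set$series)[2], length(structure_ts$phi))
  trim <- function(ts) {
    if (is.null(ts)) return(NULL)
    ts$series <- ts$series[, seq_len(nt_common), , drop = FALSE]
    ts$time <- ts$time[seq_len(nt_common)]
    ts
  }
  real_set <- trim(real_set)
  imag_set <- trim(imag_set)
  ctrl_set <- trim(ctrl_set)
  bout_ind_real <- trim(bout_ind_real)
  structure_ts$phi <- structure_ts$phi[seq_len(nt_common)]
  structure_ts$y_cos <- structure_ts$y_cos[seq_len(nt_common)]
  structure_ts$y_nsin <- structure_ts$y_nsin[seq_len(nt_common)]
  structure_ts$segment <- structure_ts$segment[seq_len(nt_common)]
  structure_ts$t <- structure_ts$t[seq_len(nt_common)]

  structure(list(mask = mask, spectra = spectra, mean_power = mean_power,
                 freqs = freqs, bands = bands, background = background,
                 bouts = bouts, bouts_by_trial = bouts_by_trial,
                 real_set = real_set, imag_set = imag_set,
                 ctrl_set = ctrl_set, bout_ind_real = bout_ind_real,
                 structure = structure_ts, anchors = anchors,
                 align = align,
                 real_trials = real_trials[align$kept],
                 imag_trials = imag_trials, ctrl_trials = ctrl_trials,
                 participant = participant, config = config),
            class = "processed_session")
}

#' @export
print.processed_session <- function(x, ...) {
  cat("Processed session:", length(x$real_trials), "real /",
      length(x$imag_trials), "imagined /", length(x$ctrl_trials),
      "control trials\n")
  for (p in names(x$bands)) {
    b <- x$bands[[p]]
    cat(sprintf("  participant %s theta band: %.1f-%.1f Hz (peak %.1f)\n",
                p, b$f_lo, b$f_hi, b$f_peak))
  }
  invisible(x)
}

## Per-channel band series: mean z-amplitude over the channel's own
## participant band bins.
channel_band_series <- function(ztf, bands, participant) {
  n_ch <- dim(ztf$amp)[1]
  nt <- dim(ztf$amp)[3]
  out <- matrix(0, n_ch, nt)
  for (cc in seq_len(n_ch)) {
    b <- bands[[as.character(participant[cc])]]
    idx <- which(ztf$freqs >= b$f_lo - 1e-9 & ztf$freqs <= b$f_hi + 1e-9)
    out[cc, ] <- if (length(idx) == 1L) ztf$amp[cc, idx, ]
                 else colMeans(ztf$amp[cc, idx, ])
  }
  out
}


## Artifact mask values at the decimated TF sample times of one trial.
decimate_mask <- function(mask, idx, fs, fs_tf, n_out) {
  t_out <- (seq_len(n_out) - 1L) / fs_tf
  sel <- pmin(round(t_out * fs) + 1L, length(idx))
  mask[idx[sel]]
}
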