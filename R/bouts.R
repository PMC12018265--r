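#' Fit the 1/f background spectrum for bout detection
#'
#' Robust linear regression (Huber M-estimator) of log mean power on log
#' frequency, one fit per channel, following the BOSC family of oscillation
#' detectors. Under the background model the power at each frequency is
#' distributed as the fitted mean times chi-squared(2)/2, so the detection
#' threshold is the fitted background power scaled by the 0.95 chi-squared
#' quantile.
#'
#' @param mean_power `channel x frequency` matrix of mean wavelet power
#'   (squared amplitude, not z-scored) over artifact-free samples.
#' @param freqs frequency grid (Hz).
#' @param n_seconds seconds of data behind the average; fewer than 10 s is
#'   an error (insufficient data).
#' @param exclude_f optional `c(lo, hi)` frequency range excluded from the
#'   regression (e.g. a strong oscillatory peak).
#' @param ci level of the detection threshold (default 0.95).
#' @return An object of class `background_fit`: list with `slope`,
#'   `intercept` (per channel, log-log), `threshold` (`channel x frequency`
#'   power thresholds), `freqs`, `ci`.
#' @export
fit_background <- function(mean_power, freqs, n_seconds = Inf,
                           exclude_f = NULL, ci = 0.95) {
  if (is.vector(mean_power)) mean_power <- matrix(mean_power, nrow = 1L)
  stopifnot(ncol(mean_power) == length(freqs))
  if (n_seconds < 10) {
    stop("insufficient data for background fit (< 10 s unmasked)",
         call. = FALSE)
  }
  use <- rep(TRUE, length(freqs))
  if (!is.null(exclude_f)) {
    use <- !(freqs >= exclude_f[1] & freqs <= exclude_f[2])
  }
  lf <- log(freqs)
  n_ch <- nrow(mean_power)
  slope <- intercept <- numeric(n_ch)
  threshold <- matrix(0, n_ch, length(freqs))
  scale <- qchisq(ci, df = 2) / 2
  for (cc in seq_len(n_ch)) {
    fit <- MASS::rlm(log(mean_power[cc, use]) ~ lf[use], maxit = 100)
    intercept[cc] <- coef(fit)[1]
    slope[cc] <- coef(fit)[2]
    threshold[cc, ] <- exp(intercept[cc] + slope[cc] * lf) * scale
  }
  structure(list(slope = slope, intercept = intercept, threshold = threshold,
                 freqs = freqs, ci = ci),
            class = "background_fit")
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf("Background fit: %d channel(s), slope %.2f to %.2f (log-log)\n",
              length(x$slope), min(x$slope), max(x$slope)))
  invisible(x)
}

#' Detect transient oscillatory bouts
#'
#' A bout (oscillatory episode) is a run of wavelet power exceeding the
#' frequency-specific background threshold for at least two cycles
#' (duration >= 2/f). Detection runs per channel and frequency bin. Episode
#' edges are first corrected for the detection wavelet's temporal smearing
#' (an above-threshold run produced by a finite burst extends beyond the
#' burst by roughly `sigma_t * qnorm(1 - threshold/peak)` on each side,
#' where `sigma_t = sqrt(tb) / (2 pi f)` is the wavelet's temporal SD);
#' the duration criterion applies to the corrected episodes. Samples
#' flagged in the artifact mask break episode runs (a bout cannot span an
#' artifact).
#'
#' Prevalence follows the BOSC Pepisode convention: the fraction of
#' unmasked time covered by episodes, averaged over the band's frequency
#' bins. Band-level `intervals` merge overlapping per-frequency episodes
#' per channel (used for indicator series and pre-turn coverage).
#'
#' @param tf a raw (not z-scored) `tf_amplitude` whose frequency grid covers
#'   the band (power = amplitude squared). For detection a short wavelet
#'   (time-bandwidth ~36, i.e. the 6-cycle convention of the BOSC family)
#'   gives the sharpest episode boundaries.
#' @param bg a [fit_background()] result on the same channels/frequencies.
#' @param band a `band_definition` or numeric `c(f_lo, f_hi)` limiting the
#'   frequencies scanned.
#' @param mask optional logical artifact vector (length = samples).
#' @param t0 time of the first sample (s), for interval bookkeeping.
#' @param min_cycles minimum duration in cycles (default 2).
#' @param wavelet_tb time-bandwidth product of the wavelet behind `tf`,
#'   used for the smearing correction; set `NULL` to disable the
#'   correction.
#' @return An object of class `bout_set`: list with `intervals` (band-level
#'   merged; data frame: channel, start_s, stop_s, mean_amp), `episodes`
#'   (per-frequency; data frame: channel, freq, start_s, stop_s, mean_amp),
#'   `prevalence` (Pepisode percent per channel), `mean_duration` (s, per
#'   channel, over per-frequency episodes), `n_samples`, `fs`, `t0`.
#' @export
detect_bouts <- function(tf, bg, band, mask = NULL, t0 = 0, min_cycles = 2,
                         wavelet_tb = 36) {
  stopifnot(inherits(tf, "tf_amplitude"), !isTRUE(tf$zscored),
            inherits(bg, "background_fit"))
  rng <- if (inherits(band, "band_definition")) c(band$f_lo, band$f_hi)
         else as.numeric(band)
  fidx <- which(tf$freqs >= rng[1] - 1e-9 & tf$freqs <= rng[2] + 1e-9)
  if (length(fidx) == 0L) stop("band is empty", call. = FALSE)
  bidx <- match(round(log(tf$freqs[fidx]), 9),
                round(log(bg$freqs), 9))
  if (anyNA(bidx)) {
    stop("`bg` frequency grid does not cover the band", call. = FALSE)
  }
  fs <- tf$fs
  n_ch <- dim(tf$amp)[1]
  nt <- dim(tf$amp)[3]
  if (is.null(mask)) mask <- rep(FALSE, nt)
  n_unmasked <- max(sum(!mask), 1L)

  ivs <- vector("list", n_ch)
  eps <- vector("list", n_ch * length(fidx))
  ei <- 0L
  prevalence <- mean_duration <- numeric(n_ch)
  for (cc in seq_len(n_ch)) {
    det <- rep(FALSE, nt)
    pep <- 0
    durs <- amps <- numeric()
    for (k in seq_along(fidx)) {
      f <- tf$freqs[fidx[k]]
      thr_amp <- sqrt(bg$threshold[cc, bidx[k]])
      a <- tf$amp[cc, fidx[k], ]
      supra <- a > thr_amp & !mask
      min_len <- ceiling(min_cycles / f * fs)
      r <- rle(supra)
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sigma_t <- if (is.null(wavelet_tb)) 0 else
        sqrt(wavelet_tb) / (2 * pi * f)
      kept <- matrix(integer(), 0, 2)
      for (i in which(r$values)) {
        s0 <- starts[i]
        s1 <- ends[i]
        if (sigma_t > 0) {
          peak <- max(a[s0:s1])
          trim <- round(sigma_t * fs *
                        stats::qnorm(1 - min(thr_amp / peak, 0.5)))
          s0 <- s0 + trim
          s1 <- s1 - trim
        }
        if (s1 - s0 + 1L >= min_len) kept <- rbind(kept, c(s0, s1))
      }
      if (nrow(kept) == 0L) next
      for (i in seq_len(nrow(kept))) det[kept[i, 1]:kept[i, 2]] <- TRUE
      ep_amp <- vapply(seq_len(nrow(kept)), function(i) {
        mean(a[kept[i, 1]:kept[i, 2]])
      }, numeric(1))
      pep <- pep + sum(kept[, 2] - kept[, 1] + 1L)
      durs <- c(durs, (kept[, 2] - kept[, 1] + 1L) / fs)
      amps <- c(amps, ep_amp)
      ei <- ei + 1L
      eps[[ei]] <- data.frame(channel = cc, freq = f,
                              start_s = t0 + (kept[, 1] - 1L) / fs,
                              stop_s = t0 + kept[, 2] / fs,
                              mean_amp = ep_amp)
    }
    prevalence[cc] <- 100 * pep / (length(fidx) * n_unmasked)
    mean_duration[cc] <- if (length(durs)) mean(durs) else NA_real_
    iv <- runs_to_intervals(det, fs, channel = cc, t0 = t0)
    if (!is.null(iv)) {
      iv$mean_amp <- vapply(seq_len(nrow(iv)), function(b) {
        idx <- sample_range(iv$start_s[b] - t0, iv$stop_s[b] - t0, fs, nt)
        mean(tf$amp[cc, fidx, idx])
      }, numeric(1))
    }
    ivs[[cc]] <- iv
  }
  intervals <- do.call(rbind, ivs)
  if (is.null(intervals)) {
    intervals <- data.frame(channel = integer(), start_s = numeric(),
                            stop_s = numeric(), mean_amp = numeric())
  }
  episodes <- if (ei > 0L) do.call(rbind, eps[seq_len(ei)]) else
    data.frame(channel = integer(), freq = numeric(), start_s = numeric(),
               stop_s = numeric(), mean_amp = numeric())
  structure(list(intervals = intervals, episodes = episodes,
                 prevalence = prevalence,
                 mean_duration = mean_duration, n_samples = nt, fs = fs,
                 t0 = t0),
            class = "bout_set")
}

#' @export
print.bout_set <- function(x, ...) {
  cat(sprintf(
    "Bout set: %d interval(s), prevalence %.1f%%, mean duration %.3f s\n",
    nrow(x$intervals), mean(x$prevalence), mean(x$mean_duration, na.rm = TRUE)))
  invisible(x)
}

#' Merge per-trial bout sets
#'
#' @param bout_list list of `bout_set` objects (e.g. one per trial) sharing
#'   channels and sampling rate.
#' @return a combined `bout_set` with pooled intervals and
#'   duration-weighted prevalence.
#' @export
combine_bouts <- function(bout_list) {
  stopifnot(length(bout_list) >= 1L)
  ns <- vapply(bout_list, `[[`, 0, "n_samples")
  w <- ns / sum(ns)
  prev <- Reduce(`+`, Map(function(b, wi) b$prevalence * wi, bout_list, w))
  intervals <- do.call(rbind, lapply(bout_list, `[[`, "intervals"))
  episodes <- do.call(rbind, lapply(bout_list, `[[`, "episodes"))
  dur <- episodes$stop_s - episodes$start_s
  mean_dur <- vapply(seq_along(prev), function(cc) {
    mean(dur[episodes$channel == cc])
  }, numeric(1))
  structure(list(intervals = intervals, episodes = episodes,
                 prevalence = prev,
                 mean_duration = mean_dur, n_samples = sum(ns),
                 fs = bout_list[[1L]]$fs, t0 = bout_list[[1L]]$t0),
            class = "bout_set")
}

#' Bout indicator series
#'
#' @param bouts a `bout_set` (or its `intervals` data frame).
#' @param channel channel number.
#' @param n number of samples of the output.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first output sample (s).
#' @return logical vector: `TRUE` where a bout covers the sample.
#' @export
bout_indicator <- function(bouts, channel, n, fs, t0 = 0) {
  iv <- if (inherits(bouts, "bout_set")) bouts$intervals else bouts
  iv <- iv[iv$channel == channel, , drop = FALSE]
  ind <- rep(FALSE, n)
  for (b in seq_len(nrow(iv))) {
    ind[sample_range(iv$start_s[b] - t0, iv$stop_s[b] - t0, fs, n)] <- TRUE
  }
  ind
}

#' Percent of trials with a bout, per warped time point
#'
#' Computes, on the common (warped) trial timeline, the percentage of trials
#' in which a bout was detected at each time point, per channel. Per-trial
#' bout indicators are warped like any other series, so fractional coverage
#' near warp boundaries is averaged.
#'
#' @param ind_warped `trial x time x channel` array of (possibly fractional)
#'   bout indicators on the common timeline, e.g. a [warp_trials()] result
#'   built from [bout_indicator()] series.
#' @return `channel x time` matrix of percentages in `[0, 100]`.
#' @export
bout_rate_timecourse <- function(ind_warped) {
  if (inherits(ind_warped, "trial_set")) ind_warped <- ind_warped$series
  stopifnot(length(dim(ind_warped)) == 3L)
  if (dim(ind_warped)[1] == 0L) stop("zero trials", call. = FALSE)
  100 * t(apply(ind_warped, c(2, 3), mean))
}

#' Bout prevalence in the pre-turn window
#'
#' Fraction of the `window_s` seconds leading up to each turn that is
#' covered by detected bouts, averaged over turns and trials, per channel.
#' Windows extending before the trial start are clipped with a warning.
#'
#' @param bouts a `bout_set` with intervals in session time.
#' @param trials data frame with `start_s` per trial.
#' @param turn_times list (one per trial) of turn times in session seconds.
#' @param window_s window length before each turn (default 2 s).
#' @param n_channels number of channels (defaults to the maximum channel
#'   index present).
#' @return numeric vector: mean pre-turn coverage in `[0, 1]` per channel.
#' @export
preturn_prevalence <- function(bouts, trials, turn_times, window_s = 2,
                               n_channels = NULL) {
  iv <- if (inherits(bouts, "bout_set")) bouts$intervals else bouts
  if (is.null(n_channels)) n_channels <- max(iv$channel, 1L)
  clipped <- FALSE
  cov <- matrix(NA_real_, 0, n_channels)
  for (i in seq_along(turn_times)) {
    for (tt in turn_times[[i]]) {
      w0 <- tt - window_s
      if (w0 < trials$start_s[i]) {
        clipped <- TRUE
        w0 <- trials$start_s[i]
      }
      if (tt <= w0) next
      row <- vapply(seq_len(n_channels), function(cc) {
        sub <- iv[iv$channel == cc & iv$stop_s > w0 & iv$start_s < tt, ,
                  drop = FALSE]
        if (nrow(sub) == 0L) return(0)
        sum(pmin(sub$stop_s, tt) - pmax(sub$start_s, w0)) / (tt - w0)
      }, numeric(1))
      cov <- rbind(cov, row)
    }
  }
  if (clipped) warning("pre-turn window clipped at trial start")
  colMeans(cov)
}
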