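#' Simulate a synthetic recording session
#'
#' Generates a complete session with the statistical structure the analysis
#' pipeline assumes: real-world walking trials along a segmented route,
#' imagined-navigation trials whose internal timing is a distorted copy of
#' the real timing, and control (treadmill-only) trials with no
#' position-locked structure. Multichannel field potentials contain a
#' 1/f^alpha Gaussian background, continuous delta and beta components,
#' intermittent theta bouts whose occurrence rate and envelope follow
#' `a + b * cos(phi(t) - phase_pref)` for each channel (phi = relative
#' position within the current route segment), and injected interictal spike
#' artifacts. All ground truth (bout intervals, artifact intervals, phase
#' anchors, warp distortions) is recorded.
#'
#' Imagined-trial timing is distorted by a participant-level shift of each
#' turn anchor (SD `imag_stretch_sd`, shared across a participant's trials
#' and channels) plus smaller per-trial jitter (SD `imag_jitter_sd`), both
#' truncated at `max_warp_s`. The systematic participant-level component is
#' what the decoder's per-participant alignment step can learn from training
#' trials.
#'
#' @param cfg a [synth_config()].
#' @param route a [route_template()]; defaults to the four-turn route built
#'   from `seed`.
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   sessions.
#' @return An object of class `session_bundle`: list with
#'   * `signals`: `channel x sample` matrix,
#'   * `fs`: neural sampling rate,
#'   * `channels`: data frame (channel, participant, region, phase_pref,
#'     theta_freq),
#'   * `trials`: data frame (trial, condition, start_s, stop_s, duration),
#'   * `trajectories`: list of [simulate_trajectory()] outputs (real trials),
#'   * `ground_truth`: list with `bouts`, `ied`, `anchors` (per trial: real =
#'     numeric vector of session-time anchors; imagined = participant x
#'     anchor matrix), `participant_shift` (injected participant-level anchor
#'     shifts),
#'   * `route`, `cfg`.
#' @export
simulate_session <- function(cfg = synth_config(), route = NULL,
                             seed = cfg$rng_seed) {
  if (is.null(route)) route <- route_template(4L, "left", seed = seed)
  trajectories <- lapply(seq_len(cfg$n_real), function(i) {
    simulate_trajectory(route, cfg, trial_seed = derive_seed(seed, i))
  })
  simulate_ieeg(route, trajectories, cfg, seed = derive_seed(seed, 100000L))
}

#' Simulate the neural portion of a session from given trajectories
#'
#' Core generator behind [simulate_session()]; see that help page for the
#' signal model. Exposed separately so that trajectories (and hence the
#' behavioural ground truth) can be controlled directly.
#'
#' @param route a [route_template()].
#' @param trajectories list of real-trial [simulate_trajectory()] outputs
#'   sharing `route`.
#' @param cfg a [synth_config()].
#' @param seed integer seed for the neural generator.
#' @return A `session_bundle`; see [simulate_session()].
#' @export
simulate_ieeg <- function(route, trajectories, cfg = synth_config(),
                          seed = cfg$rng_seed) {
  stopifnot(inherits(route, "route_template"), length(trajectories) >= 1L)
  fs <- cfg$fs_neural
  if (any(vapply(trajectories, function(tr) attr(tr, "fs"), 0) !=
          cfg$fs_motion)) {
    stop("trajectory sampling rates do not match `cfg$fs_motion`",
         call. = FALSE)
  }
  n_real <- length(trajectories)
  cond_real <- paste0("real_", route$handedness)
  cond_imag <- paste0("imag_", route$handedness)

  with_seed(seed, {
    ## ---- trial timing -------------------------------------------------
    real_anchors_rel <- lapply(trajectories, trajectory_anchors)
    real_dur <- vapply(real_anchors_rel, max, 0)
    n_anch <- route$n_turns + 2L
    mean_anchors <- colMeans(do.call(rbind, real_anchors_rel))
    mean_dur <- mean_anchors[n_anch]

    ## participant-level systematic distortion of imagined timing
    part_shift <- matrix(0, cfg$n_participants, n_anch)
    if (cfg$n_imag > 0) {
      part_shift[, 2:(n_anch - 1L)] <- trunc_norm(
        cfg$n_participants * (n_anch - 2L), cfg$imag_stretch_sd,
        cfg$max_warp_s)
    }

    imag_dur <- if (cfg$n_imag > 0) mean_dur * rnorm(cfg$n_imag, 1, 0.04)
                else numeric()
    ctrl_dur <- if (cfg$n_control > 0) mean_dur * rnorm(cfg$n_control, 1, 0.05)
                else numeric()

    conditions <- c(rep(cond_real, n_real),
                    rep("control", cfg$n_control),
                    rep(cond_imag, cfg$n_imag))
    durations <- c(real_dur, ctrl_dur, imag_dur)
    n_trials <- length(durations)
    starts <- cfg$gap_s + c(0, cumsum(head(durations, -1) + cfg$gap_s))
    stops <- starts + durations
    trials <- data.frame(trial = seq_len(n_trials), condition = conditions,
                         start_s = starts, stop_s = stops,
                         duration = durations)
    n_total <- ceiling((stops[n_trials] + cfg$gap_s) * fs)

    ## ---- phase anchors per trial (session time) -----------------------
    anchors <- vector("list", n_trials)
    for (i in seq_len(n_real)) {
      anchors[[i]] <- starts[i] + real_anchors_rel[[i]]
    }
    imag_idx <- which(conditions == cond_imag)
    for (k in seq_along(imag_idx)) {
      i <- imag_idx[k]
      base <- mean_anchors / mean_dur * durations[i]
      jit <- c(0, trunc_norm(n_anch - 2L, cfg$imag_jitter_sd,
                             cfg$max_warp_s), 0)
      am <- matrix(0, cfg$n_participants, n_anch)
      for (p in seq_len(cfg$n_participants)) {
        ## total distortion (systematic + trial jitter) capped at the
        ## alignment limit
        shift <- pmin(pmax(part_shift[p, ] + jit, -cfg$max_warp_s),
                      cfg$max_warp_s)
        am[p, ] <- starts[i] + enforce_monotone(base + shift, durations[i],
                                                min_gap = 0.3)
      }
      anchors[[i]] <- am
    }

    ## ---- background + continuous components ---------------------------
    signals <- matrix(0, cfg$n_channels, n_total)
    tt <- (seq_len(n_total) - 1L) / fs
    for (cc in seq_len(cfg$n_channels)) {
      bg <- one_over_f_noise(n_total, fs, cfg$background_exponent)
      d_am <- pmax(0.2, 1 + 0.5 * slow_am(n_total, fs))
      b_am <- pmax(0.2, 1 + 0.5 * slow_am(n_total, fs))
      signals[cc, ] <- bg +
        cfg$delta_amp * d_am * sin(2 * pi * cfg$delta_freq * tt +
                                   runif(1, 0, 2 * pi)) +
        cfg$beta_amp * b_am * sin(2 * pi * cfg$beta_freq * tt +
                                  runif(1, 0, 2 * pi))
    }

    ## ---- theta bouts --------------------------------------------------
    gt_bouts <- vector("list", n_trials * cfg$n_channels)
    gi <- 0L
    for (i in seq_len(n_trials)) {
      n_i <- round(durations[i] * fs)
      t_rel <- (seq_len(n_i) - 1L) / fs
      off <- round(starts[i] * fs)
      seg_idx <- off + seq_len(n_i)
      block <- signals[, seg_idx, drop = FALSE]
      ## per-participant phase series for this trial (NULL for control)
      phi_p <- vector("list", cfg$n_participants)
      if (conditions[i] != "control") {
        for (p in seq_len(cfg$n_participants)) {
          a <- if (is.matrix(anchors[[i]])) anchors[[i]][p, ]
               else anchors[[i]]
          phi_p[[p]] <- phase_from_anchors(a - starts[i], t_rel)
        }
      }
      for (cc in seq_len(cfg$n_channels)) {
        p <- cfg$participant[cc]
        f_th <- cfg$theta_freq[p]
        m <- if (is.null(phi_p[[p]])) rep(cfg$mod_a, n_i)
             else cfg$mod_a + cfg$mod_b * cos(phi_p[[p]] -
                                              cfg$channel_phase_pref[cc])
        bouts <- place_bouts(m, fs,
                             target_cov = cfg$bout_fraction,
                             dur_mean = cfg$bout_duration_mean,
                             dur_sd = cfg$bout_duration_sd,
                             dur_min = 2 / f_th + 0.02)
        if (is.null(bouts)) next
        for (b in seq_len(nrow(bouts))) {
          i0 <- floor(bouts[b, 1] * fs) + 1L
          i1 <- min(ceiling(bouts[b, 2] * fs), n_i)
          idx <- i0:i1
          tau <- (idx - 1L) / fs
          amp <- cfg$channel_gain[cc] * cfg$bout_amp_snr * m[idx] /
            (cfg$mod_a + cfg$mod_b)
          wave <- amp * sin(2 * pi * f_th * tau + runif(1, 0, 2 * pi)) *
            bout_taper(length(idx), fs)
          block[cc, idx] <- block[cc, idx] + wave
        }
        gi <- gi + 1L
        gt_bouts[[gi]] <- data.frame(channel = cc, trial = i,
                                     start_s = starts[i] + bouts[, 1],
                                     stop_s = starts[i] + bouts[, 2])
      }
      signals[, seg_idx] <- block
    }
    gt_bouts <- do.call(rbind, gt_bouts[seq_len(gi)])
    if (is.null(gt_bouts)) {
      gt_bouts <- data.frame(channel = integer(), trial = integer(),
                             start_s = numeric(), stop_s = numeric())
    }

    ## ---- interictal discharges ---------------------------------------
    total_s <- n_total / fs
    n_ied <- rpois(1, cfg$ied_rate * total_s / 60)
    ied_times <- sort(runif(n_ied, 1, total_s - 1))
    gt_ied <- data.frame(start_s = numeric(), stop_s = numeric())
    if (n_ied > 0) {
      w <- ied_waveform(fs, cfg$ied_amp)
      for (et in ied_times) {
        i0 <- round(et * fs)
        idx <- i0 + seq_along(w)
        gains <- runif(cfg$n_channels, 0.85, 1.15)
        signals[, idx] <- signals[, idx] +
          outer(gains, w)
      }
      gt_ied <- data.frame(start_s = ied_times,
                           stop_s = ied_times + length(w) / fs)
    }

    channels <- data.frame(
      channel = seq_len(cfg$n_channels),
      participant = cfg$participant,
      region = rep("MTL", cfg$n_channels),
      phase_pref = cfg$channel_phase_pref,
      gain = cfg$channel_gain,
      theta_freq = cfg$theta_freq[cfg$participant])
  })

  structure(list(signals = signals, fs = fs, channels = channels,
                 trials = trials, trajectories = trajectories,
                 ground_truth = list(bouts = gt_bouts, ied = gt_ied,
                                     anchors = anchors,
                                     participant_shift = part_shift,
                                     mean_anchors = mean_anchors),
                 route = route, cfg = cfg),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("Session bundle:", nrow(x$signals), "channels,",
      nrow(x$trials), "trials,",
      sprintf("%.0f s @ %g Hz\n", ncol(x$signals) / x$fs, x$fs))
  print(table(x$trials$condition))
  invisible(x)
}

#' Ground-truth phase series of a trial
#'
#' @param session a `session_bundle`.
#' @param trial trial number.
#' @param participant participant number (matters for imagined trials, whose
#'   timing is participant specific).
#' @return list with `t` (session seconds) and `phi` (radians in
#'   `[0, 2*pi)`); `phi` is `NA` for control trials.
#' @export
true_phase <- function(session, trial, participant = 1L) {
  tr <- session$trials[trial, ]
  n <- round(tr$duration * session$fs)
  t_rel <- (seq_len(n) - 1L) / session$fs
  a <- session$ground_truth$anchors[[trial]]
  if (is.null(a)) {
    return(list(t = tr$start_s + t_rel, phi = rep(NA_real_, n)))
  }
  if (is.matrix(a)) a <- a[participant, ]
  list(t = tr$start_s + t_rel,
       phi = phase_from_anchors(a - tr$start_s, t_rel))
}

#' Simulate a single-channel signal with injected oscillatory bouts
#'
#' Minimal generator for calibrating the bout detector: 1/f^alpha Gaussian
#' background (unit SD) plus sinusoidal bouts of amplitude
#' `snr x background SD` at the given intervals, with 50 ms Hann ramps.
#'
#' @param duration_s signal length (s).
#' @param fs sampling rate (Hz).
#' @param intervals matrix with columns start/stop (s), or NULL for pure
#'   background.
#' @param freq bout frequency (Hz).
#' @param snr bout amplitude in background-SD units.
#' @param alpha background spectral exponent.
#' @param seed integer seed.
#' @return numeric signal vector.
#' @export
simulate_bout_signal <- function(duration_s, fs, intervals = NULL,
                                 freq = 6.5, snr = 3, alpha = 1.5,
                                 seed = 1L) {
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- one_over_f_noise(n, fs, alpha)
    if (!is.null(intervals)) {
      for (b in seq_len(nrow(intervals))) {
        idx <- sample_range(intervals[b, 1], intervals[b, 2], fs, n)
        tau <- (idx - 1L) / fs
        x[idx] <- x[idx] + snr * sin(2 * pi * freq * tau +
                                     runif(1, 0, 2 * pi)) *
          bout_taper(length(idx), fs)
      }
    }
    x
  })
}

#' Simulate warped band-amplitude trials directly
#'
#' Reduced generator that skips the waveform level entirely and emits
#' band-amplitude trials on a common timeline: each structured trial is the
#' channel's position modulation `cos(phi(t) - pref)` scaled by `snr / 2`
#' plus smooth unit-SD noise; control trials are noise only. Used to
#' calibrate the consistency statistics at scale.
#'
#' @param n_trials trials per condition.
#' @param nt samples per trial.
#' @param fs sampling rate of the timeline (Hz).
#' @param n_segments route segments spanned by the timeline.
#' @param pref preferred phase of the channel (radians).
#' @param snr modulation-to-noise ratio (signal amplitude = snr/2).
#' @param structured FALSE for control trials (no phase-locked component).
#' @param seed integer seed.
#' @return `trial x time` matrix.
#' @export
simulate_band_trials <- function(n_trials, nt, fs = 50, n_segments = 5,
                                 pref = 0, snr = 2, structured = TRUE,
                                 seed = 1L) {
  phi <- wrap_phase(2 * pi * n_segments * (seq_len(nt) - 1L) / nt)
  sig <- if (structured) (snr / 2) * cos(phi - pref) else numeric(nt)
  with_seed(seed, {
    t(vapply(seq_len(n_trials), function(i) {
      e <- gauss_smooth(rnorm(nt), fs, 0.3)
      e <- e / max(sd(e), 1e-12)
      sig + e
    }, numeric(nt)))
  })
}

## ---- internal helpers ---------------------------------------------------

## Piecewise-linear phase: 0 at each anchor, advancing to 2*pi at the next.
phase_from_anchors <- function(anchors, t) {
  k <- length(anchors)
  seg <- pmin(pmax(findInterval(t, anchors), 1L), k - 1L)
  frac <- (t - anchors[seg]) / (anchors[seg + 1L] - anchors[seg])
  wrap_phase(2 * pi * pmin(pmax(frac, 0), 1))
}

## Zero-mean truncated normal draws.
trunc_norm <- function(n, sd, cap) {
  if (n == 0L) return(numeric())
  pmin(pmax(rnorm(n, 0, sd), -cap), cap)
}

## Force anchor sequence to start at 0, end at `dur`, with minimum spacing.
enforce_monotone <- function(a, dur, min_gap = 0.3) {
  a[1] <- 0
  a[length(a)] <- dur
  for (i in 2:length(a)) a[i] <- max(a[i], a[i - 1] + min_gap)
  a[length(a)] <- dur
  for (i in (length(a) - 1L):1L) a[i] <- min(a[i], a[i + 1L] - min_gap)
  a[1] <- 0
  a
}

## Slowly varying unit-SD modulation: smooth noise generated at a low rate
## (correlation time ~2 s) and linearly interpolated to the signal grid.
slow_am <- function(n, fs, fs_low = 10) {
  n_low <- ceiling(n / fs * fs_low) + 2L
  z <- gauss_smooth(rnorm(n_low), fs_low, 2)
  z <- z / max(sd(z), 1e-12)
  approx(seq(0, by = 1 / fs_low, length.out = n_low), z,
         xout = (seq_len(n) - 1L) / fs)$y
}

## Gaussian 1/f^alpha noise via spectral shaping, unit SD. The spectrum is
## rolled off outside the recording bandwidth (1-90 Hz by default),
## mimicking the acquisition hardware's band limits; without this the
## sub-1 Hz tail of the power law would dominate the variance.
one_over_f_noise <- function(n, fs, alpha, band = c(1, 90)) {
  nfft <- nextn(n, c(2, 3))
  X <- fft(rnorm(nfft))
  f <- (0:(nfft - 1L)) * fs / nfft
  f <- pmin(f, fs - f)
  S <- c(0, f[-1]^(-alpha / 2))
  hp <- pmin(pmax((f - band[1] / 2) / band[1], 0), 1)
  lp <- pmin(pmax((band[2] + 10 - f) / 10, 0), 1)
  S <- S * hp * lp
  x <- Re(fft(X * S, inverse = TRUE)[seq_len(n)] / nfft)
  x / sd(x)
}

## Place non-overlapping bout intervals with start density proportional to
## `m` and total coverage close to `target_cov`. Returns a matrix with
## columns start_s, stop_s (trial-relative), or NULL.
place_bouts <- function(m, fs, target_cov, dur_mean, dur_sd, dur_min,
                        margin = 0.1) {
  n <- length(m)
  dur_trial <- n / fs
  n_bouts <- round(target_cov * dur_trial / dur_mean)
  if (n_bouts < 1L) return(NULL)
  cdf <- cumsum(pmax(m, 0))
  cdf <- cdf / cdf[n]
  taken <- matrix(numeric(), 0, 2)
  for (b in seq_len(n_bouts)) {
    dur <- max(dur_min, rnorm(1, dur_mean, dur_sd))
    for (att in seq_len(50L)) {
      start <- (findInterval(runif(1), cdf) + 1L) / fs - dur / 2
      start <- min(max(start, 0), dur_trial - dur)
      if (start < 0) break
      ok <- nrow(taken) == 0L ||
        all(start >= taken[, 2] + margin | start + dur <= taken[, 1] - margin)
      if (ok) {
        taken <- rbind(taken, c(start, start + dur))
        break
      }
    }
  }
  if (nrow(taken) == 0L) NULL else taken[order(taken[, 1]), , drop = FALSE]
}

## Hann on/off ramps (50 ms) so bouts start and stop smoothly.
bout_taper <- function(n, fs, ramp_s = 0.05) {
  r <- min(round(ramp_s * fs), floor(n / 2))
  w <- rep(1, n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    w[seq_len(r)] <- ramp
    w[n - seq_len(r) + 1L] <- ramp
  }
  w
}

## Interictal discharge: 70 ms biphasic spike followed by a 300 ms slow wave.
ied_waveform <- function(fs, amp) {
  t1 <- seq(0, 0.07, by = 1 / fs)
  spike <- amp * sin(2 * pi * t1 / 0.07)
  t2 <- seq(0, 0.3, by = 1 / fs)
  slow <- -0.35 * amp * sin(pi * t2 / 0.3)
  c(spike, slow[-1])
}
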