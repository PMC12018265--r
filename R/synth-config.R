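#' Configuration for the synthetic-session generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' study conditions the pipeline is designed for: 250 Hz field potentials
#' from 18 bipolar MTL channels across 5 participants, 120 Hz motion capture,
#' intermittent theta bouts whose occurrence and envelope are locked to the
#' relative position within route segments, a 1/f background with delta and
#' beta components, and injected interictal spike artifacts.
#'
#' @param fs_neural neural sampling rate in Hz.
#' @param fs_motion motion-capture sampling rate in Hz.
#' @param n_channels number of recording channels.
#' @param n_participants number of participants; channels are split across
#'   participants as evenly as possible.
#' @param channel_phase_pref per-channel preferred phase in radians within
#'   `[0, 2*pi)`; defaults to uniform spacing so that the population tiles the
#'   segment with cosine- and -sine-like modulations.
#' @param channel_gain per-channel multiplier on the bout amplitude,
#'   constant across conditions; the default heterogeneous pattern emulates
#'   anatomy (strongly modulated hippocampal sites next to weakly modulated
#'   MTL sites), which is what makes temporal consistency spatially
#'   correlated between conditions.
#' @param theta_freq per-participant theta frequency in Hz (4-9); defaults to
#'   evenly spaced values in 4.5-8.5 Hz.
#' @param bout_amp_snr amplitude of theta bouts relative to the background
#'   standard deviation (dimensionless).
#' @param bout_fraction target fraction of real-trial time covered by bouts.
#' @param bout_duration_mean,bout_duration_sd bout duration distribution (s).
#' @param mod_a,mod_b offset and depth of the position modulation
#'   `a + b * cos(phi - pref)` of bout rate and envelope.
#' @param background_exponent spectral exponent alpha of the 1/f^alpha
#'   Gaussian background.
#' @param delta_freq,delta_amp,beta_freq,beta_amp frequency (Hz) and amplitude
#'   (in background-SD units) of continuous delta and beta components.
#' @param ied_rate interictal-discharge rate in events per minute.
#' @param ied_amp spike amplitude in background-SD units.
#' @param imag_stretch_sd SD (s) of the participant-level anchor shifts that
#'   distort imagined trials (truncated at `max_warp_s`).
#' @param imag_jitter_sd SD (s) of the additional per-trial anchor jitter.
#' @param max_warp_s cap on any injected anchor shift (s); matches the
#'   decoder's alignment cap.
#' @param n_real,n_imag,n_control trials per condition.
#' @param speed_base baseline walking speed (m/s).
#' @param traj_jitter_sd lateral trajectory jitter SD (m).
#' @param smooth_window_s Gaussian smoothing window for motion signals (s).
#' @param gap_s inter-trial gap of background-only recording (s).
#' @param rng_seed integer seed; identical configs and seeds give
#'   bit-identical sessions.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(fs_neural = 250, fs_motion = 120,
                         n_channels = 18L, n_participants = 5L,
                         channel_phase_pref = NULL, channel_gain = NULL,
                         theta_freq = NULL,
                         bout_amp_snr = 2, bout_fraction = 0.21,
                         bout_duration_mean = 0.52, bout_duration_sd = 0.08,
                         mod_a = 1, mod_b = 0.8,
                         background_exponent = 1.5,
                         delta_freq = 2, delta_amp = 0.5,
                         beta_freq = 16, beta_amp = 0.4,
                         ied_rate = 1, ied_amp = 8,
                         imag_stretch_sd = 0.75, imag_jitter_sd = 0.25,
                         max_warp_s = 2,
                         n_real = 24L, n_imag = 24L, n_control = 24L,
                         speed_base = 1.35, traj_jitter_sd = 0.15,
                         smooth_window_s = 0.2, gap_s = 2,
                         rng_seed = 1L) {
  n_channels <- as.integer(n_channels)
  n_participants <- as.integer(n_participants)
  if (n_participants > n_channels) {
    stop("need at least one channel per participant", call. = FALSE)
  }
  if (is.null(channel_phase_pref)) {
    channel_phase_pref <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  }
  if (length(channel_phase_pref) != n_channels ||
      any(channel_phase_pref < 0 | channel_phase_pref >= 2 * pi)) {
    stop("`channel_phase_pref` must give one value in [0, 2*pi) per channel",
         call. = FALSE)
  }
  if (is.null(channel_gain)) {
    channel_gain <- rep_len(c(1, 0.45, 0.8, 0.55, 0.95, 0.65),
                            n_channels)
  }
  if (length(channel_gain) != n_channels || any(channel_gain < 0)) {
    stop("`channel_gain` must give one nonnegative value per channel",
         call. = FALSE)
  }
  if (is.null(theta_freq)) {
    theta_freq <- if (n_participants == 1L) 6.5 else
      seq(4.5, 8.5, length.out = n_participants)
  }
  if (length(theta_freq) != n_participants ||
      any(theta_freq < 4 | theta_freq > 9)) {
    stop("`theta_freq` must give one value in [4, 9] Hz per participant",
         call. = FALSE)
  }
  max_f <- max(theta_freq, delta_freq, beta_freq)
  if (fs_neural <= 2 * max_f) {
    stop("`fs_neural` must exceed twice the highest simulated frequency",
         call. = FALSE)
  }
  ## channel -> participant map, sizes as even as possible (e.g. 4,4,4,3,3)
  sizes <- rep(n_channels %/% n_participants, n_participants)
  extra <- n_channels %% n_participants
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  participant <- rep(seq_len(n_participants), times = sizes)
  cfg <- list(
    fs_neural = fs_neural, fs_motion = fs_motion,
    n_channels = n_channels, n_participants = n_participants,
    participant = participant,
    channel_phase_pref = channel_phase_pref,
    channel_gain = channel_gain, theta_freq = theta_freq,
    bout_amp_snr = bout_amp_snr, bout_fraction = bout_fraction,
    bout_duration_mean = bout_duration_mean,
    bout_duration_sd = bout_duration_sd,
    mod_a = mod_a, mod_b = mod_b,
    background_exponent = background_exponent,
    delta_freq = delta_freq, delta_amp = delta_amp,
    beta_freq = beta_freq, beta_amp = beta_amp,
    ied_rate = ied_rate, ied_amp = ied_amp,
    imag_stretch_sd = imag_stretch_sd, imag_jitter_sd = imag_jitter_sd,
    max_warp_s = max_warp_s,
    n_real = as.integer(n_real), n_imag = as.integer(n_imag),
    n_control = as.integer(n_control),
    speed_base = speed_base, traj_jitter_sd = traj_jitter_sd,
    smooth_window_s = smooth_window_s, gap_s = gap_s,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic session config:", x$n_channels, "channels /",
      x$n_participants, "participants @", x$fs_neural, "Hz\n")
  cat("  trials: ", x$n_real, " real, ", x$n_imag, " imagined, ",
      x$n_control, " control; bout SNR ", x$bout_amp_snr,
      ", target coverage ", x$bout_fraction, "\n", sep = "")
  invisible(x)
}
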