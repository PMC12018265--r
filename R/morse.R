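#' Morse-wavelet time-frequency amplitude
#'
#' Continuous wavelet transform with generalized Morse wavelets (symmetry
#' parameter gamma = 3, time-bandwidth product P^2 = 60, i.e. beta = 20),
#' evaluated as an FFT filter bank on a log-spaced frequency grid with 10
#' voices per octave over 1-90 Hz by default. Wavelets use bandpass
#' normalization (peak value 2 in the frequency domain), so a unit-amplitude
#' sinusoid yields amplitude ~1 at its frequency bin.
#'
#' Signals are zero-padded on both sides before transforming; the first and
#' last ~2 s of each trial should be treated as cone-of-influence and are
#' excluded from normalization statistics by [zscore_amplitude()].
#'
#' @param signals numeric vector, or matrix with one channel per row.
#' @param fs sampling rate in Hz.
#' @param f_range frequency range in Hz (default `c(1, 90)`).
#' @param voices voices per octave (default 10).
#' @param gamma,beta Morse parameters; defaults gamma = 3, beta = 20
#'   (time-bandwidth product `gamma * beta = 60`).
#' @param fs_out output sampling rate of the amplitude time axis (defaults
#'   to `fs`). Amplitude envelopes are band limited far below the signal
#'   rate, so a decimated output (e.g. 50 Hz) loses nothing.
#' @return An object of class `tf_amplitude`: list with `amp`
#'   (`channel x frequency x time` nonnegative array), `freqs` (Hz, log
#'   spaced, strictly increasing), `fs` (the output rate) and
#'   `zscored = FALSE`.
#' @examples
#' x <- sin(2 * pi * 8 * seq(0, 10, by = 1 / 250))
#' tf <- morse_tf_amplitude(x, 250)
#' tf$freqs[which.max(tf$amp[1, , 1250])]  # ~8 Hz
#' @export
morse_tf_amplitude <- function(signals, fs, f_range = c(1, 90), voices = 10,
                               gamma = 3, beta = 20, fs_out = fs) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  if (anyNA(signals) || any(!is.finite(signals))) {
    stop("`signals` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  n_ch <- nrow(signals)
  n <- ncol(signals)
  n_out <- if (fs_out == fs) n else floor((n - 1L) / fs * fs_out) + 1L
  freqs <- morse_freq_grid(f_range, voices)

  pad <- round(fs)                       # 1 s zero padding each side
  nfft <- nextn(n + 2L * pad, c(2, 3))
  X <- matrix(0, nfft, n_ch)
  X[pad + seq_len(n), ] <- t(signals)
  X <- mvfft(X)

  ## Each wavelet's frequency response occupies a narrow positive band, so
  ## the inverse transform is computed from the spectral slice covering its
  ## support only (zero-padded 2x for band-limited interpolation of the
  ## modulus), then linearly interpolated onto the signal grid. This is
  ## exact up to the truncation of the response below 1e-8 of its peak.
  n_pos <- floor(nfft / 2) + 1L
  f_bins <- (seq_len(n_pos) - 1L) * fs / nfft
  amp <- array(0, dim = c(n_ch, length(freqs), n_out))
  keep_t <- pad / fs + (seq_len(n_out) - 1L) / fs_out
  for (k in seq_along(freqs)) {
    u <- f_bins / freqs[k]
    H <- numeric(n_pos)
    posi <- u > 0
    H[posi] <- 2 * exp(beta * log(u[posi]) -
                       (beta / gamma) * (u[posi]^gamma - 1))
    sup <- which(H > 2e-8)
    if (length(sup) < 2L) {
      stop("wavelet at ", freqs[k], " Hz unresolved on the FFT grid",
           call. = FALSE)
    }
    k0 <- sup[1L]
    k1 <- sup[length(sup)]
    mcore <- k1 - k0 + 1L
    m2 <- nextn(2L * mcore, c(2, 3))
    Z <- matrix(0+0i, m2, n_ch)
    Z[seq_len(mcore), ] <- X[k0:k1, , drop = FALSE] * H[k0:k1]
    A <- Mod(mvfft(Z, inverse = TRUE)) / nfft
    ## interpolate the decimated modulus onto the output sample times
    step_d <- nfft / fs / m2
    cwt_fill(amp, A, keep_t / step_d, k - 1L, n_ch, length(freqs))
  }
  structure(list(amp = amp, freqs = freqs, fs = fs_out, zscored = FALSE),
            class = "tf_amplitude")
}

#' Log-spaced wavelet frequency grid
#'
#' Frequencies `f_lo * 2^(k/voices)` for `k = 0, 1, ...` up to `f_hi`.
#'
#' @param f_range `c(f_lo, f_hi)` in Hz.
#' @param voices voices per octave.
#' @return numeric vector of frequencies (Hz).
#' @export
morse_freq_grid <- function(f_range = c(1, 90), voices = 10) {
  stopifnot(length(f_range) == 2L, f_range[1] > 0, f_range[2] > f_range[1])
  k_max <- floor(voices * log2(f_range[2] / f_range[1]) + 1e-9)
  f_range[1] * 2^((0:k_max) / voices)
}

#' @export
print.tf_amplitude <- function(x, ...) {
  d <- dim(x$amp)
  cat("TF amplitude: ", d[1], " channel(s) x ", d[2], " frequencies (",
      sprintf("%.2f", min(x$freqs)), "-", sprintf("%.2f", max(x$freqs)),
      " Hz) x ", d[3], " samples @ ", x$fs, " Hz",
      if (isTRUE(x$zscored)) " [z-scored]", "\n", sep = "")
  invisible(x)
}
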