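#' Detect interictal epileptiform discharges (IEDs)
#'
#' Flags pathological spike transients using two amplitude criteria: the
#' envelope of the broadband (1-90 Hz) signal and the envelope of the
#' 15-80 Hz band-passed signal, each thresholded at `thresh_mult` (default 5)
#' times its per-channel session median. Flagged runs are extended by
#' `extend_s` (default 256 ms) on both sides to capture up- and down-ramping
#' activity, and a trial whose flagged coverage exceeds `exclude_frac`
#' (default 50%) of its duration is marked excluded. A sample flagged on any
#' channel masks all channels for downstream statistics.
#'
#' Envelopes are the modulus of the analytic signal; band-passing is
#' performed in the frequency domain with raised-cosine transitions (2 Hz),
#' which is zero-phase by construction.
#'
#' @param signals `channel x sample` matrix.
#' @param fs sampling rate in Hz.
#' @param trials optional data frame with `start_s`, `stop_s` columns; when
#'   given, per-trial excluded flags are computed.
#' @param thresh_mult threshold as a multiple of the median envelope.
#' @param extend_s extension of flagged runs on each side, seconds.
#' @param exclude_frac flagged-coverage fraction above which a trial is
#'   excluded.
#' @return An object of class `artifact_mask`: list with `mask` (logical per
#'   sample, union over channels), `intervals` (data frame: channel,
#'   start_s, stop_s), `ied_fraction` (percent of samples flagged),
#'   `trial_excluded` (logical per trial, if `trials` given), `fs`.
#' @export
detect_ied <- function(signals, fs, trials = NULL, thresh_mult = 5,
                       extend_s = 0.256, exclude_frac = 0.5) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  n <- ncol(signals)
  if (n < fs) stop("signal must be at least 1 s long", call. = FALSE)
  n_ch <- nrow(signals)
  ext <- round(extend_s * fs)

  mask <- rep(FALSE, n)
  ivs <- vector("list", n_ch)
  nfft <- nextn(n, c(2, 3))
  for (cc in seq_len(n_ch)) {
    X <- fft(c(signals[cc, ], numeric(nfft - n)))
    env_bb <- envelope_from_fft(X, n, fs, c(1, 90))
    env_hf <- envelope_from_fft(X, n, fs, c(15, 80))
    flag <- env_bb > thresh_mult * median(env_bb) |
            env_hf > thresh_mult * median(env_hf)
    flag <- extend_runs(flag, ext)
    mask <- mask | flag
    ivs[[cc]] <- runs_to_intervals(flag, fs, channel = cc)
  }
  intervals <- do.call(rbind, ivs)
  if (is.null(intervals)) {
    intervals <- data.frame(channel = integer(), start_s = numeric(),
                            stop_s = numeric())
  }
  out <- list(mask = mask,
              intervals = intervals,
              ied_fraction = 100 * mean(mask),
              fs = fs)
  if (!is.null(trials)) {
    out$trial_excluded <- vapply(seq_len(nrow(trials)), function(i) {
      idx <- sample_range(trials$start_s[i], trials$stop_s[i], fs, n)
      mean(mask[idx]) > exclude_frac
    }, logical(1))
  }
  class(out) <- "artifact_mask"
  out
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("Artifact mask: %.2f%% of samples flagged, %d interval(s)\n",
              x$ied_fraction, nrow(x$intervals)))
  if (!is.null(x$trial_excluded)) {
    cat("  trials excluded:", sum(x$trial_excluded), "of",
        length(x$trial_excluded), "\n")
  }
  invisible(x)
}

## Envelope (analytic-signal modulus) of a frequency band, via FFT:
## multiply positive frequencies by 2 * raised-cosine band mask, zero the
## negative frequencies, inverse transform.
band_envelope <- function(x, fs, band, transition = 2) {
  n <- length(x)
  nfft <- nextn(n, c(2, 3))
  X <- fft(c(x, numeric(nfft - n)))
  envelope_from_fft(X, n, fs, band, transition)
}

envelope_from_fft <- function(X, n, fs, band, transition = 2) {
  nfft <- length(X)
  pos <- seq_len(floor(nfft / 2) + 1L)
  fp <- (pos - 1L) * fs / nfft
  H <- numeric(nfft)
  ramp_up <- pmin(pmax((fp - (band[1] - transition / 2)) / transition, 0), 1)
  ramp_dn <- pmin(pmax(((band[2] + transition / 2) - fp) / transition, 0), 1)
  H[pos] <- 2 * ramp_up * ramp_dn
  H[1] <- 0                              # analytic signal: drop DC
  a <- fft(X * H, inverse = TRUE)[seq_len(n)] / nfft
  Mod(a)
}

## Extend TRUE runs of `flag` by `ext` samples on both sides.
extend_runs <- function(flag, ext) {
  if (ext <= 0 || !any(flag)) return(flag)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- flag
  n <- length(flag)
  for (i in which(r$values)) {
    out[max(1L, starts[i] - ext):min(n, ends[i] + ext)] <- TRUE
  }
  out
}

## Convert a logical flag vector into a data frame of [start_s, stop_s)
## intervals (half-open, 0-based time).
runs_to_intervals <- function(flag, fs, channel = NA_integer_, t0 = 0) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  if (length(i) == 0L) return(NULL)
  data.frame(channel = channel,
             start_s = t0 + (starts[i] - 1L) / fs,
             stop_s = t0 + ends[i] / fs)
}

## Sample indices (1-based) covering [start_s, stop_s) at rate fs, clipped.
sample_range <- function(start_s, stop_s, fs, n) {
  i0 <- max(1L, floor(start_s * fs) + 1L)
  i1 <- min(n, ceiling(stop_s * fs))
  if (i1 < i0) integer() else i0:i1
}
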