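#' Z-score time-frequency amplitudes
#'
#' Normalizes amplitudes per (channel, frequency) to mean 0 and SD 1 over the
#' session, so signal strengths are comparable across recording channels.
#' Statistics are computed over unmasked samples outside the cone of
#' influence (the first/last `edge_s` seconds of each trial); masked and edge
#' samples are transformed with the same parameters.
#'
#' `tf_session_stats()` computes the pooled statistics across a list of
#' per-trial `tf_amplitude` objects, and `zscore_amplitude()` applies them
#' (computing them from the single input when `stats` is omitted).
#'
#' @param tf a `tf_amplitude` (not yet z-scored).
#' @param mask optional logical vector (length = samples, `TRUE` = artifact)
#'   of samples to exclude from the statistics.
#' @param edge_s cone-of-influence margin in seconds (default 2).
#' @param stats optional list with `mu` and `sigma` (`channel x frequency`
#'   matrices) from [tf_session_stats()].
#' @return `zscore_amplitude()`: the `tf_amplitude` with `zscored = TRUE`.
#'   `tf_session_stats()`: list with `mu`, `sigma`, `n` (samples used).
#' @export
zscore_amplitude <- function(tf, mask = NULL, edge_s = 2, stats = NULL) {
  stopifnot(inherits(tf, "tf_amplitude"))
  if (isTRUE(tf$zscored)) stop("`tf` is already z-scored", call. = FALSE)
  if (is.null(stats)) {
    stats <- tf_session_stats(list(tf), list(mask), edge_s = edge_s)
  }
  ## (channel, frequency) statistics recycle exactly over the first two
  ## dimensions of the (channel x frequency x time) array
  tf$amp <- (tf$amp - as.vector(stats$mu)) / as.vector(stats$sigma)
  tf$zscored <- TRUE
  tf
}

#' @rdname zscore_amplitude
#' @param tf_list list of per-trial `tf_amplitude` objects (same channels and
#'   frequency grid).
#' @param mask_list optional list of per-trial logical masks.
#' @export
tf_session_stats <- function(tf_list, mask_list = NULL, edge_s = 2) {
  stopifnot(length(tf_list) >= 1L)
  d <- dim(tf_list[[1L]]$amp)
  fs <- tf_list[[1L]]$fs
  s1 <- matrix(0, d[1], d[2])
  s2 <- matrix(0, d[1], d[2])
  n_used <- 0L
  for (i in seq_along(tf_list)) {
    tf <- tf_list[[i]]
    nt <- dim(tf$amp)[3]
    edge <- min(round(edge_s * fs), floor((nt - 1) / 2))
    use <- rep(TRUE, nt)
    if (edge > 0) use[c(seq_len(edge), nt - seq_len(edge) + 1L)] <- FALSE
    m <- if (is.null(mask_list)) NULL else mask_list[[i]]
    if (!is.null(m)) use <- use & !m
    if (!any(use)) next
    n_use <- sum(use)
    if (n_use > nt / 2) {
      ## cheaper to sum everything and subtract the excluded columns
      s1 <- s1 + rowSums(tf$amp, dims = 2L)
      s2 <- s2 + rowSums(tf$amp^2, dims = 2L)
      if (n_use < nt) {
        a <- tf$amp[, , !use, drop = FALSE]
        s1 <- s1 - rowSums(a, dims = 2L)
        s2 <- s2 - rowSums(a^2, dims = 2L)
      }
    } else {
      a <- tf$amp[, , use, drop = FALSE]
      s1 <- s1 + rowSums(a, dims = 2L)
      s2 <- s2 + rowSums(a^2, dims = 2L)
    }
    n_used <- n_used + n_use
  }
  if (n_used < 2L) stop("no usable samples for z-scoring", call. = FALSE)
  mu <- s1 / n_used
  sigma <- sqrt(pmax(s2 / n_used - mu^2, 0) * n_used / (n_used - 1))
  if (any(sigma < 1e-12)) {
    stop("zero variance at some (channel, frequency); cannot z-score",
         call. = FALSE)
  }
  list(mu = mu, sigma = sigma, n = n_used)
}

#' Individualized frequency band from a mean amplitude spectrum
#'
#' Identifies the spectral peak as the largest strict local maximum (over a
#' +/- 1 bin neighbourhood, ties broken toward the lower frequency) within
#' the search range, then walks outward to the neighbouring lower and higher
#' spectral minima, which set the exact band edges. Used with a 3-12 Hz
#' search range to individualize the theta band per participant.
#'
#' @param spectrum numeric vector: mean amplitude (or power) per frequency.
#' @param freqs frequency grid in Hz (log spaced, strictly increasing).
#' @param search_lo,search_hi search range in Hz (defaults 3 and 12).
#' @return An object of class `band_definition`: list with `f_peak`, `f_lo`,
#'   `f_hi` (Hz), `band_name` and the bin indices `idx` of the band.
#' @export
find_individual_band <- function(spectrum, freqs, search_lo = 3,
                                 search_hi = 12) {
  stopifnot(length(spectrum) == length(freqs), !is.unsorted(freqs))
  n <- length(spectrum)
  in_range <- which(freqs >= search_lo & freqs <= search_hi)
  in_range <- in_range[in_range > 1L & in_range < n]
  ## strict over the left neighbour, >= over the right: plateau ties resolve
  ## toward the lower frequency
  is_max <- vapply(in_range, function(i) {
    spectrum[i] > spectrum[i - 1L] && spectrum[i] >= spectrum[i + 1L]
  }, logical(1))
  if (!any(is_max)) {
    stop("no local maximum in [", search_lo, ", ", search_hi, "] Hz",
         call. = FALSE)
  }
  cand <- in_range[is_max]
  peak <- cand[which.max(spectrum[cand])]

  i_lo <- peak
  while (i_lo > 1L && spectrum[i_lo - 1L] < spectrum[i_lo]) i_lo <- i_lo - 1L
  i_hi <- peak
  while (i_hi < n && spectrum[i_hi + 1L] < spectrum[i_hi]) i_hi <- i_hi + 1L

  f_peak <- freqs[peak]
  band_name <- if (f_peak < 3) "delta" else if (f_peak <= 12) "theta"
               else "beta"
  structure(list(f_peak = f_peak, f_lo = freqs[i_lo], f_hi = freqs[i_hi],
                 band_name = band_name, idx = i_lo:i_hi, peak_idx = peak),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("%s band: peak %.2f Hz, range %.2f-%.2f Hz (%d bins)\n",
              x$band_name, x$f_peak, x$f_lo, x$f_hi, length(x$idx)))
  invisible(x)
}

#' Average time-frequency amplitude over a band
#'
#' @param tf a `tf_amplitude`.
#' @param band a `band_definition`, or a numeric `c(f_lo, f_hi)` range.
#' @return `channel x time` matrix of band-mean amplitudes.
#' @export
band_average <- function(tf, band) {
  stopifnot(inherits(tf, "tf_amplitude"))
  rng <- if (inherits(band, "band_definition")) c(band$f_lo, band$f_hi)
         else as.numeric(band)
  idx <- which(tf$freqs >= rng[1] - 1e-9 & tf$freqs <= rng[2] + 1e-9)
  if (length(idx) == 0L) {
    stop("band contains no frequency bins of `tf`", call. = FALSE)
  }
  out <- apply(tf$amp[, idx, , drop = FALSE], c(1, 3), mean)
  dimnames(out) <- NULL
  out
}
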