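#' Build the circular task structure of a route
#'
#' Abstracts the route into a circular variable: within each inter-anchor
#' span (route segment) the phase phi advances linearly from 0 at segment
#' entry to 2*pi at the turn ending the segment. The two response channels
#' are `y_cos = cos(phi)` (peaked at each turn) and `y_nsin = -sin(phi)`
#' (peaked at 3/4 of each segment, i.e. before turns).
#'
#' @param anchors strictly increasing anchor times (s): trial start, turns,
#'   trial end.
#' @param fs sampling rate of the structure timeline (Hz).
#' @return An object of class `task_structure`: list with `t`, `phi`,
#'   `y_cos`, `y_nsin`, `segment`, `anchors`, `fs`, `n_turns`.
#' @export
build_task_structure <- function(anchors, fs) {
  if (length(anchors) < 2L) {
    stop("need at least 2 anchors (start and end)", call. = FALSE)
  }
  if (is.unsorted(anchors, strictly = TRUE)) {
    stop("anchors must be strictly increasing", call. = FALSE)
  }
  t <- seq(anchors[1], anchors[length(anchors)], by = 1 / fs)
  phi <- phase_from_anchors(anchors - anchors[1], t - anchors[1])
  seg <- pmin(pmax(findInterval(t, anchors), 1L), length(anchors) - 1L)
  structure(list(t = t, phi = phi, y_cos = cos(phi), y_nsin = -sin(phi),
                 segment = seg, anchors = anchors, fs = fs,
                 n_turns = length(anchors) - 2L),
            class = "task_structure")
}

#' Phase from decoded cosine / negative-sine components
#'
#' The relative position is the angle of the resultant vector of the two
#' orthogonal components: `phi = atan2(-y_nsin, y_cos)` mapped to
#' `[0, 2*pi)`. Returns `NA` where both components are (numerically) zero.
#'
#' @param y_cos,y_nsin decoded component values.
#' @return phase estimates in `[0, 2*pi)`.
#' @export
phase_from_components <- function(y_cos, y_nsin) {
  phi <- wrap_phase(atan2(-y_nsin, y_cos))
  phi[abs(y_cos) < 1e-12 & abs(y_nsin) < 1e-12] <- NA_real_
  phi
}

#' Fit the cross-validated linear position decoder
#'
#' Ordinary least squares from the pooled channel amplitudes (all channels,
#' all participants, one design matrix with intercept) to the two task
#' responses `(cos phi, -sin phi)`. Trials are assigned whole to folds;
#' within each fold, weights come from the training trials only and
#' predictions are emitted only for the held-out trials. The default scheme
#' is 10 folds repeated 10 times. A rank-deficient design falls back to a
#' lightly regularized solve with a warning.
#'
#' @param X `sample x channel` predictor matrix (z-scored band amplitudes),
#'   rows pooled over trials.
#' @param y `sample x 2` response matrix, or a `task_structure` whose
#'   `(y_cos, y_nsin)` are recycled per trial.
#' @param trial_id integer vector: trial of each row of `X`.
#' @param folds,repeats cross-validation scheme (default 10 x 10).
#' @param seed optional integer seed for the fold assignment.
#' @return An object of class `decoder_model`: list with `weights`
#'   (`(n_channels + 1) x 2`, full-data fit), `cv_pred` (`sample x 2` mean
#'   held-out prediction across repeats), `fold_id` (`trial x repeats`
#'   matrix), `folds`, `repeats`, `trial_id`.
#' @export
fit_decoder <- function(X, y, trial_id, folds = 10L, repeats = 10L,
                        seed = NULL) {
  X <- as.matrix(X)
  if (inherits(y, "task_structure")) {
    y <- per_trial_response(y, trial_id)
  }
  y <- as.matrix(y)
  stopifnot(nrow(X) == nrow(y), nrow(X) == length(trial_id), ncol(y) == 2L)
  trials <- sort(unique(trial_id))
  n_tr <- length(trials)
  folds <- min(folds, n_tr)

  run <- function() {
    pred <- matrix(0, nrow(X), 2L)
    fold_id <- matrix(0L, n_tr, repeats)
    for (rep_i in seq_len(repeats)) {
      fid <- sample(rep_len(seq_len(folds), n_tr))
      fold_id[, rep_i] <- fid
      for (f in seq_len(folds)) {
        test_tr <- trials[fid == f]
        test <- trial_id %in% test_tr
        W <- ols_solve(cbind(1, X[!test, , drop = FALSE]),
                       y[!test, , drop = FALSE])
        pred[test, ] <- pred[test, ] +
          cbind(1, X[test, , drop = FALSE]) %*% W
      }
    }
    list(pred = pred / repeats, fold_id = fold_id)
  }
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  W_full <- ols_solve(cbind(1, X), y)
  structure(list(weights = W_full, cv_pred = r$pred, fold_id = r$fold_id,
                 folds = folds, repeats = repeats, trial_id = trial_id,
                 trials = trials),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("Linear position decoder: %d channels, %d x %d CV over %d trials\n",
              nrow(x$weights) - 1L, x$folds, x$repeats, length(x$trials)))
  invisible(x)
}

## OLS with ridge fallback for rank-deficient designs.
ols_solve <- function(A, y) {
  fit <- tryCatch(qr.coef(qr(A), y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) {
    warning("rank-deficient design: using ridge fallback")
    lambda <- 1e-6 * sum(diag(crossprod(A))) / ncol(A)
    fit <- solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, y))
  }
  fit
}

## Stack the structure responses once per trial, matching `trial_id` rows.
per_trial_response <- function(structure, trial_id) {
  n_per <- length(structure$phi)
  y1 <- structure$y_cos
  y2 <- structure$y_nsin
  counts <- table(trial_id)
  if (any(counts != n_per)) {
    stop("rows per trial do not match the structure timeline", call. = FALSE)
  }
  cbind(rep(y1, length(counts)), rep(y2, length(counts)))
}

#' Predict decoded components and phase for new data
#'
#' @param model a `decoder_model`.
#' @param X `sample x channel` matrix on the same channels as the training
#'   data.
#' @param channels optional channel subset (column indices used from the
#'   pooled weight matrix); other channels are treated as at their mean
#'   (zero after z-scoring). Used for the per-participant marginal estimates
#'   that drive imagined-trial alignment.
#' @return list with `y_cos`, `y_nsin`, `phi` (radians in `[0, 2*pi)`).
#' @export
predict_decoder <- function(model, X, channels = NULL) {
  X <- as.matrix(X)
  W <- model$weights
  if (is.null(channels)) {
    stopifnot(ncol(X) == nrow(W) - 1L)
    comp <- cbind(1, X) %*% W
  } else {
    stopifnot(ncol(X) == length(channels))
    comp <- cbind(1, X) %*% W[c(1L, channels + 1L), , drop = FALSE]
  }
  list(y_cos = comp[, 1], y_nsin = comp[, 2],
       phi = phase_from_components(comp[, 1], comp[, 2]))
}

#' Summarize reconstruction accuracy
#'
#' Computes circular reconstruction errors `wrap(phi_hat - phi)` in
#' `(-pi, pi]`, their histogram in degrees, and the 2D density of actual
#' versus estimated positions over `n_bins x n_bins` phase bins, normalized
#' so that a uniform estimate has density 1 everywhere (values are factors
#' over chance).
#'
#' @param phi_hat,phi estimated and actual phase series (radians), equal
#'   length; `NA`s are dropped pairwise.
#' @param n_bins phase bins per axis (>= 4, default 20).
#' @return An object of class `reconstruction_result`: list with `errors`
#'   (radians), `mean_abs_err_deg`, `resultant` (mean resultant length of
#'   the errors), `circ_mean_deg`, `density` (`actual x estimated` matrix,
#'   mean 1), `hist` (data frame: mid_deg, prop), `n`.
#' @export
reconstruction_report <- function(phi_hat, phi, n_bins = 20L) {
  if (n_bins < 4L) stop("`n_bins` must be >= 4", call. = FALSE)
  stopifnot(length(phi_hat) == length(phi))
  ok <- is.finite(phi_hat) & is.finite(phi)
  phi_hat <- wrap_phase(phi_hat[ok])
  phi <- wrap_phase(phi[ok])
  err <- wrap_angle(phi_hat - phi)
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1L)
  bin <- function(x) pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                          n_bins)
  dens <- table(factor(bin(phi), levels = seq_len(n_bins)),
                factor(bin(phi_hat), levels = seq_len(n_bins)))
  dens <- unclass(dens) / length(phi) * n_bins^2
  eb <- seq(-180, 180, by = 360 / n_bins)
  eh <- hist(err * 180 / pi, breaks = eb, plot = FALSE)
  structure(list(errors = err,
                 mean_abs_err_deg = mean(abs(err)) * 180 / pi,
                 resultant = resultant_length(err),
                 circ_mean_deg = circ_mean(err) * 180 / pi,
                 density = dens,
                 hist = data.frame(mid_deg = eh$mids,
                                   prop = eh$counts / length(err)),
                 n = length(err)),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "Reconstruction: mean |error| = %.1f deg, resultant = %.3f (n = %d)\n",
    x$mean_abs_err_deg, x$resultant, x$n))
  invisible(x)
}

#' Circular-shift permutation null for reconstruction accuracy
#'
#' Tests whether reconstruction errors cluster around a preferred angle by
#' comparing the mean resultant length of the errors against a null obtained
#' by circularly time-shifting the estimated series relative to the actual
#' one (whole-series rotations, preserving autocorrelation).
#'
#' @param phi_hat,phi estimated and actual phase series (radians).
#' @param n_shifts number of random shifts (default 10000).
#' @param seed optional integer seed.
#' @return A `permutation_result` with `statistic` = mean resultant length
#'   (one-sided p).
#' @export
circular_shift_null <- function(phi_hat, phi, n_shifts = 10000L,
                                seed = NULL) {
  stopifnot(length(phi_hat) == length(phi))
  n <- length(phi)
  if (n < 10L) stop("series must have at least 10 samples", call. = FALSE)
  obs <- resultant_length(wrap_angle(phi_hat - phi))
  run <- function() {
    shifts <- sample.int(n - 1L, n_shifts, replace = TRUE)
    vapply(shifts, function(s) {
      resultant_length(wrap_angle(phi_hat[c((s + 1L):n, 1L:s)] - phi))
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- (1 + sum(null >= obs)) / (n_shifts + 1)
  structure(list(statistic = obs, p = p, null = null, cohens_d = NULL,
                 ci = NULL, n_perm = n_shifts, alternative = "greater"),
            class = "permutation_result")
}

#' Cross-correlogram of band dynamics with the route structure
#'
#' Correlates a segment-length-normalized amplitude series with the -sine
#' task structure at circular lags up to +/- the number of segments. On
#' structured data the correlogram shows a central peak and side peaks at
#' multiples of one segment length, reflecting the repetition of theta
#' dynamics across segments.
#'
#' @param x amplitude series on the segment-normalized timeline (e.g. from
#'   [normalize_segment_lengths()]).
#' @param y_nsin the -sine structure on the same timeline.
#' @param seg_len samples per segment.
#' @param max_lag_segments maximal lag in segments (default: the full
#'   series).
#' @return data frame with `lag_s` (in segments), `r` (correlation); the
#'   row at lag 0 is the structure correlation.
#' @export
crosscorrelogram_route <- function(x, y_nsin, seg_len,
                                   max_lag_segments = NULL) {
  stopifnot(length(x) == length(y_nsin))
  n <- length(x)
  n_seg <- n / seg_len
  if (is.null(max_lag_segments)) max_lag_segments <- floor(n_seg)
  lags <- seq(-max_lag_segments * seg_len, max_lag_segments * seg_len)
  r <- vapply(lags, function(l) {
    idx <- ((seq_len(n) - 1L + l) %% n) + 1L
    cor(x, y_nsin[idx])
  }, numeric(1))
  data.frame(lag_seg = lags / seg_len, r = r)
}

#' Cross-validated reconstruction report for warped real trials
#'
#' Averages the held-out predictions of a fitted decoder across trials on
#' the common timeline (every trial's prediction comes from folds where it
#' was held out) and summarizes the reconstruction against the task
#' structure.
#'
#' @param model a `decoder_model` fitted on rows ordered trial-major, each
#'   trial spanning the structure timeline.
#' @param structure the `task_structure` the model was trained against.
#' @return list with `report` (a `reconstruction_result`), `phi_hat` (the
#'   trial-averaged held-out phase estimate) and `comp_mean`.
#' @export
decode_cv_report <- function(model, structure) {
  nt <- length(structure$phi)
  n_tr <- length(model$trial_id) / nt
  stopifnot(n_tr == round(n_tr))
  comp <- cbind(rowMeans(matrix(model$cv_pred[, 1], nt, n_tr)),
                rowMeans(matrix(model$cv_pred[, 2], nt, n_tr)))
  phi_hat <- phase_from_components(comp[, 1], comp[, 2])
  list(report = reconstruction_report(phi_hat, structure$phi),
       phi_hat = phi_hat, comp_mean = comp)
}

#' Decode imagined trials with cross-validated alignment
#'
#' Applies a decoder trained on real-world walking to imagined-navigation
#' trials. Because imagined velocity is unobservable, an initial position
#' estimate is aligned to the task structure with capped DTW (default
#' +/- 2 s). The alignment is learned per participant on the training folds
#' (from the participant's channels' marginal estimate, averaged over
#' training trials) and applied unchanged to the held-out trials' channel
#' series, preserving relative timing between a participant's channels; the
#' pooled model then decodes the aligned data. The scheme is 10 folds
#' repeated 10 times.
#'
#' @param model a `decoder_model` trained on real trials.
#' @param trial_set a [warp_trials()] result: imagined (or control) trials
#'   linearly warped to the common timeline (`trial x time x channel`).
#' @param structure the `task_structure` on the same timeline.
#' @param participant integer vector: participant of each channel.
#' @param cap_s DTW cap in seconds (default 2).
#' @param folds,repeats cross-validation scheme (default 10 x 10).
#' @param seed optional integer seed.
#' @return list with `report` (a `reconstruction_result` over all held-out
#'   samples), `phi_hat_mean` (aligned estimate averaged over trials and
#'   repeats), `mean_offsets_s` (participant x repeat mean alignment
#'   offsets), `edge_flag` (TRUE if any learned path was pinned to the band
#'   edge over half its length), `structure`.
#' @export
decode_imagined <- function(model, trial_set, structure, participant,
                            cap_s = 2, folds = 10L, repeats = 10L,
                            seed = NULL) {
  stopifnot(inherits(trial_set, "trial_set"),
            inherits(structure, "task_structure"))
  arr <- trial_set$series
  n_tr <- dim(arr)[1]
  nt <- dim(arr)[2]
  n_ch <- dim(arr)[3]
  stopifnot(length(structure$phi) == nt, length(participant) == n_ch)
  fs <- trial_set$fs
  parts <- sort(unique(participant))
  folds <- min(folds, n_tr)

  run <- function() {
    phi_all <- matrix(NA_real_, nt, repeats)
    comp_sum <- matrix(0, nt, 2L)
    offsets <- matrix(NA_real_, length(parts), repeats)
    edge_flag <- FALSE
    for (rep_i in seq_len(repeats)) {
      fid <- sample(rep_len(seq_len(folds), n_tr))
      comp_rep <- matrix(0, nt, 2L)
      for (f in seq_len(folds)) {
        test <- which(fid == f)
        train <- which(fid != f)
        aligned <- arr[test, , , drop = FALSE]
        for (pi in seq_along(parts)) {
          ch <- which(participant == parts[pi])
          ## marginal estimate from this participant's channels, averaged
          ## over training trials on the common timeline
          Xtr <- colMeans(arr[train, , ch, drop = FALSE], dims = 1L)
          est <- predict_decoder(model, Xtr, channels = ch)
          wp <- capped_dtw_align(est$phi, structure$phi, fs, cap_s = cap_s)
          if (wp$edge_frac > 0.5) edge_flag <- TRUE
          if (f == 1L) offsets[pi, rep_i] <- wp$mean_offset_s
          for (ti in seq_along(test)) {
            aligned[ti, , ch] <- t(apply_warp_path(
              wp, t(aligned[ti, , ch, drop = TRUE])))
          }
        }
        for (ti in seq_along(test)) {
          est <- predict_decoder(model, aligned[ti, , ])
          comp_rep <- comp_rep + cbind(est$y_cos, est$y_nsin)
        }
      }
      ## held-out reconstruction of this repeat: every trial predicted from
      ## the fold where it was held out, averaged over trials
      comp_rep <- comp_rep / n_tr
      phi_all[, rep_i] <- phase_from_components(comp_rep[, 1], comp_rep[, 2])
      comp_sum <- comp_sum + comp_rep
    }
    list(phi_all = phi_all, comp_mean = comp_sum / repeats,
         offsets = offsets, edge_flag = edge_flag)
  }
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  list(report = reconstruction_report(as.vector(r$phi_all),
                                      rep(structure$phi, repeats)),
       phi_hat_mean = phase_from_components(r$comp_mean[, 1],
                                            r$comp_mean[, 2]),
       comp_mean = r$comp_mean,
       mean_offsets_s = r$offsets,
       edge_flag = r$edge_flag,
       structure = structure)
}
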