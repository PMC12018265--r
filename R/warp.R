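#' Align real walking trials and identify turns via DTW
#'
#' Trials are aligned pairwise with dynamic time warping on the 2D positions
#' (Euclidean local cost, symmetric unit-slope steps) against the medoid
#' trial (minimum summed DTW distance to all others, which avoids order
#' dependence). Turns are located on the medoid from peaks of the path
#' angular velocity and mapped through each trial's warping path, giving one
#' set of strictly increasing turn anchors per trial.
#'
#' @param trajectories list of [simulate_trajectory()]-style data frames
#'   (columns `t`, `x`, `y`), all walks of the same route.
#' @param n_turns number of turns to locate; defaults to the length of the
#'   first trajectory's `turn_times` attribute.
#' @param fs_ds sampling rate (Hz) at which positions are compared (DTW runs
#'   on decimated trajectories for speed; anchors are still returned in
#'   seconds on the original timeline).
#' @return list with `anchors` (kept-trial x (n_turns + 2) matrix of
#'   trial-relative times: start, turns, end), `medoid` (index into kept
#'   trials), `kept` (indices of trials retained; trials shorter than 50% of
#'   the median duration are dropped with a warning).
#' @export
dtw_align_trajectories <- function(trajectories, n_turns = NULL, fs_ds = 30) {
  stopifnot(length(trajectories) >= 2L)
  if (is.null(n_turns)) {
    n_turns <- length(attr(trajectories[[1L]], "turn_times"))
  }
  durs <- vapply(trajectories, function(tr) tr$t[nrow(tr)], 0)
  kept <- which(durs >= 0.5 * median(durs))
  if (length(kept) < length(trajectories)) {
    warning(length(trajectories) - length(kept),
            " trial(s) shorter than 50% of the median duration dropped")
  }
  trajectories <- trajectories[kept]
  n_tr <- length(trajectories)
  fs <- attr(trajectories[[1L]], "fs")
  if (is.null(fs)) fs <- 1 / median(diff(trajectories[[1L]]$t))
  step <- max(1L, round(fs / fs_ds))
  xy_ds <- lapply(trajectories, function(tr) {
    idx <- seq(1L, nrow(tr), by = step)
    cbind(tr$x[idx], tr$y[idx])
  })

  ## medoid by pairwise DTW distance
  dm <- matrix(0, n_tr, n_tr)
  for (i in seq_len(n_tr - 1L)) {
    for (j in (i + 1L):n_tr) {
      dm[i, j] <- dm[j, i] <- dtw_xy_dist(xy_ds[[i]], xy_ds[[j]])
    }
  }
  medoid <- which.min(rowSums(dm))

  turn_idx_med <- find_turns_xy(xy_ds[[medoid]], fs / step, n_turns)
  n_med <- nrow(xy_ds[[medoid]])

  anchors <- matrix(0, n_tr, n_turns + 2L)
  for (i in seq_len(n_tr)) {
    if (i == medoid) {
      mapped <- turn_idx_med
    } else {
      pp <- dtw_cost_path(xy_cost(xy_ds[[medoid]], xy_ds[[i]]))$path
      mapped <- approx(pp[, 1], pp[, 2], xout = turn_idx_med,
                       ties = mean, rule = 2)$y
    }
    turn_t <- (mapped - 1) * step / fs
    a <- c(0, turn_t, durs[kept[i]])
    if (is.unsorted(a, strictly = TRUE)) a <- sort(a)
    anchors[i, ] <- a
  }
  list(anchors = anchors, medoid = medoid, kept = kept)
}

## Euclidean local-cost matrix between two 2D point sequences.
xy_cost <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

## Locate `n_turns` turning points of a 2D path as the largest peaks of the
## smoothed heading angular velocity, with a minimum separation.
find_turns_xy <- function(xy, fs, n_turns, min_sep_s = 1.5) {
  heading <- atan2(diff(xy[, 2]), diff(xy[, 1]))
  dh <- abs(wrap_angle(diff(heading))) * fs
  dh <- gauss_smooth(dh, fs, 0.4)
  ord <- order(dh, decreasing = TRUE)
  sep <- round(min_sep_s * fs)
  picked <- integer()
  for (i in ord) {
    if (length(picked) == n_turns) break
    if (all(abs(picked - i) >= sep)) picked <- c(picked, i)
  }
  if (length(picked) < n_turns) {
    stop("could not locate ", n_turns, " turns on the trajectory",
         call. = FALSE)
  }
  ## refine: centre of mass of the angular-velocity bump around each peak
  refined <- vapply(sort(picked), function(pk) {
    w <- max(1L, pk - sep %/% 2):min(length(dh), pk + sep %/% 2)
    sum(w * dh[w]) / sum(dh[w])
  }, numeric(1))
  refined + 1  # diff() offset: sample index on the original grid
}

#' Piecewise-linear time warping between anchor sets
#'
#' Resamples a series so that the source anchor times map exactly onto the
#' destination anchor times, with linear interpolation of time within each
#' inter-anchor span.
#'
#' @param x numeric vector, or `channel x time` matrix, sampled at `fs` with
#'   the first sample at `anchors_src[1]`.
#' @param fs input sampling rate (Hz).
#' @param anchors_src,anchors_dst strictly increasing anchor times (s) of
#'   equal length, including the endpoints.
#' @param fs_out output sampling rate (defaults to `fs`).
#' @return the warped series on the destination timeline
#'   `seq(anchors_dst[1], max(anchors_dst), by = 1/fs_out)`, same class as
#'   the input.
#' @export
piecewise_linear_warp <- function(x, fs, anchors_src, anchors_dst,
                                  fs_out = fs) {
  if (length(anchors_src) != length(anchors_dst)) {
    stop("anchor sets must have equal length", call. = FALSE)
  }
  if (is.unsorted(anchors_src, strictly = TRUE) ||
      is.unsorted(anchors_dst, strictly = TRUE)) {
    stop("anchors must be strictly increasing", call. = FALSE)
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  t_src_grid <- anchors_src[1] + (seq_len(n) - 1L) / fs
  t_dst <- seq(anchors_dst[1], anchors_dst[length(anchors_dst)],
               by = 1 / fs_out)
  t_map <- approx(anchors_dst, anchors_src, xout = t_dst, rule = 2)$y
  t_map <- pmin(pmax(t_map, t_src_grid[1]), t_src_grid[n])
  ## the source grid is uniform, so interpolate all channels at once
  posf <- (t_map - t_src_grid[1]) * fs
  i0 <- pmin(pmax(floor(posf), 0), n - 2)
  w <- posf - i0
  out <- x[, i0 + 1L, drop = FALSE] * rep(1 - w, each = nrow(x)) +
    x[, i0 + 2L, drop = FALSE] * rep(w, each = nrow(x))
  if (vec) out[1, ] else out
}

#' Resample a series to unit-length route segments
#'
#' Each inter-anchor span (one route segment) is linearly resampled to a
#' common length, so that corresponding relative positions in different
#' segments fall on the same within-segment sample index. Used before
#' cross-correlating band dynamics with the periodic task structure.
#'
#' @param x numeric vector, or `channel x time` matrix, first sample at
#'   `anchors[1]`.
#' @param fs sampling rate (Hz).
#' @param anchors strictly increasing span boundaries (s), including the
#'   endpoints.
#' @param n_per_seg output samples per segment; defaults to the mean span
#'   duration times `fs`.
#' @return the resampled series (`n_segments * n_per_seg` samples) with
#'   attribute `seg_len = n_per_seg`.
#' @export
normalize_segment_lengths <- function(x, fs, anchors, n_per_seg = NULL) {
  spans <- diff(anchors)
  if (any(spans <= 1 / fs)) {
    stop("anchor spans must be longer than one sample", call. = FALSE)
  }
  if (is.null(n_per_seg)) n_per_seg <- max(2L, round(mean(spans) * fs))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  t_grid <- anchors[1] + (seq_len(n) - 1L) / fs
  pieces <- vector("list", length(spans))
  for (k in seq_along(spans)) {
    t_out <- seq(anchors[k], anchors[k + 1L], length.out = n_per_seg + 1L)
    t_out <- t_out[-(n_per_seg + 1L)]
    t_out <- pmin(pmax(t_out, t_grid[1]), t_grid[n])
    pieces[[k]] <- do.call(rbind, lapply(seq_len(nrow(x)), function(cc) {
      approx(t_grid, x[cc, ], xout = t_out)$y
    }))
  }
  out <- do.call(cbind, pieces)
  attr(out, "seg_len") <- as.integer(n_per_seg)
  if (vec) {
    v <- out[1, ]
    attr(v, "seg_len") <- as.integer(n_per_seg)
    v
  } else out
}

#' Capped DTW alignment of a phase series to the task structure
#'
#' Sakoe-Chiba-banded dynamic time warping between an estimated phase series
#' and the reference task-structure phase, minimizing the squared circular
#' distance. The band width equals the cap (default +/- 2 s), so no sample
#' can be shifted by more than the cap.
#'
#' @param src_phase estimated phase series (radians), source timeline.
#' @param ref_phase reference phase series (radians), target timeline; same
#'   sampling rate.
#' @param fs sampling rate of both series (Hz).
#' @param cap_s maximal allowed time shift (s); must be at least one sample.
#' @return An object of class `warp_path`: list with `path` (k x 2 matrix of
#'   source/reference sample pairs), `fs`, `cap_s`, `mean_offset_s` (mean of
#'   source minus reference time over the path), `edge_frac` (fraction of
#'   path samples pinned at the band edge) and `distance`.
#' @export
capped_dtw_align <- function(src_phase, ref_phase, fs, cap_s = 2) {
  band <- cap_s * fs
  if (band < 1) stop("`cap_s` must be at least one sample", call. = FALSE)
  res <- dtw_circ_path(wrap_phase(src_phase), wrap_phase(ref_phase),
                       band = band)
  path <- res$path
  offs <- (path[, 1] - path[, 2]) / fs
  structure(list(path = path, fs = fs, cap_s = cap_s,
                 src_len = length(src_phase), ref_len = length(ref_phase),
                 mean_offset_s = mean(offs),
                 edge_frac = mean(abs(offs) >= cap_s - 1.5 / fs),
                 distance = res$distance),
            class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf(
    "DTW warp path: %d pairs, cap %.2g s, mean offset %.3f s, %.0f%% at edge\n",
    nrow(x$path), x$cap_s, x$mean_offset_s, 100 * x$edge_frac))
  invisible(x)
}

#' Apply a DTW warp path to a series
#'
#' Maps a series from the source timeline onto the reference timeline of a
#' [capped_dtw_align()] path: each reference sample receives the mean of the
#' source samples its path pairs point to.
#'
#' @param wp a `warp_path`.
#' @param x numeric vector (length `wp$src_len`) or `channel x time` matrix.
#' @return the warped series on the reference timeline (`wp$ref_len`
#'   samples).
#' @export
apply_warp_path <- function(wp, x) {
  stopifnot(inherits(wp, "warp_path"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == wp$src_len)
  cnt <- tabulate(wp$path[, 2], nbins = wp$ref_len)
  out <- t(rowsum(t(x)[wp$path[, 1], , drop = FALSE],
                  group = wp$path[, 2])) / rep(cnt, each = nrow(x))
  if (vec) out[1, ] else out
}

#' Warp per-trial series onto a common trial timeline
#'
#' Applies [piecewise_linear_warp()] to every trial so that all trials share
#' one timeline with identical anchor times (the across-trial mean anchors
#' by default), optionally resampling to a lower output rate.
#'
#' @param series_list list (one per trial) of `channel x time` matrices on
#'   the trial-relative timeline starting at 0, sampled at `fs`.
#' @param anchors trial x n_anchor matrix of trial-relative anchor times
#'   (first column 0, last the trial duration).
#' @param fs input sampling rate (Hz).
#' @param fs_out output sampling rate (Hz).
#' @param anchors_dst common timeline anchors; defaults to `colMeans(anchors)`.
#' @param condition optional condition label stored alongside.
#' @return An object of class `trial_set`: list with `series`
#'   (`trial x time x channel` array on the common timeline), `time` (s),
#'   `anchors` (the common anchors), `anchors_src`, `fs`, `condition`.
#' @export
warp_trials <- function(series_list, anchors, fs, fs_out = fs,
                        anchors_dst = NULL, condition = NA_character_) {
  stopifnot(length(series_list) == nrow(anchors))
  if (is.null(anchors_dst)) anchors_dst <- colMeans(anchors)
  tmpl <- piecewise_linear_warp(series_list[[1L]], fs, anchors[1L, ],
                                anchors_dst, fs_out = fs_out)
  n_time <- ncol(tmpl)
  n_ch <- nrow(tmpl)
  out <- array(0, dim = c(length(series_list), n_time, n_ch))
  out[1L, , ] <- t(tmpl)
  for (i in seq_along(series_list)[-1L]) {
    w <- piecewise_linear_warp(series_list[[i]], fs, anchors[i, ],
                               anchors_dst, fs_out = fs_out)
    out[i, , ] <- t(w)
  }
  structure(list(series = out,
                 time = seq(anchors_dst[1], anchors_dst[length(anchors_dst)],
                            by = 1 / fs_out),
                 anchors = anchors_dst, anchors_src = anchors,
                 fs = fs_out, condition = condition),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf(
    "Trial set (%s): %d trials x %d samples x %d channels @ %g Hz\n",
    x$condition, d[1], d[2], d[3], x$fs))
  invisible(x)
}
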