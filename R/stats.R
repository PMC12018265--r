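#' Event-locked (turn-aligned) average
#'
#' Averages a series (or one series per trial) in windows around event
#' times, with time 0 at the event. Windows extending past the series
#' bounds are clipped (those samples contribute nothing).
#'
#' @param series numeric vector (one continuous series), or a list of
#'   per-trial vectors.
#' @param event_times event times in seconds (one vector, or a list
#'   matching `series`).
#' @param fs sampling rate (Hz).
#' @param window_s `c(before, after)` window in seconds (default
#'   `c(-3, 3)`).
#' @param t0 time of the first sample of each series (scalar or per-trial
#'   vector).
#' @return list with `lag_s` and `mean` (the event-locked average), plus
#'   `n_events`.
#' @export
turn_aligned_average <- function(series, event_times, fs,
                                 window_s = c(-3, 3), t0 = 0) {
  if (!is.list(series)) {
    series <- list(series)
    event_times <- list(event_times)
  }
  if (!is.list(event_times)) event_times <- list(event_times)
  stopifnot(length(series) == length(event_times))
  t0 <- rep_len(t0, length(series))
  lag_idx <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  acc <- numeric(length(lag_idx))
  cnt <- numeric(length(lag_idx))
  n_events <- 0L
  for (i in seq_along(series)) {
    x <- series[[i]]
    for (ev in event_times[[i]]) {
      ctr <- round((ev - t0[i]) * fs) + 1L
      idx <- ctr + lag_idx
      ok <- idx >= 1L & idx <= length(x)
      acc[ok] <- acc[ok] + x[idx[ok]]
      cnt[ok] <- cnt[ok] + 1
      n_events <- n_events + 1L
    }
  }
  if (n_events == 0L) stop("no events", call. = FALSE)
  list(lag_s = lag_idx / fs, mean = acc / pmax(cnt, 1), n_events = n_events)
}

#' Cluster-based sign-flip permutation test
#'
#' Tests where the across-channel mean of event-locked maps deviates from
#' zero, correcting over time (and frequency) points via cluster-level
#' statistics: a sign-flip null is built by flipping randomly selected
#' halves of the channels and averaging; points beyond the two-sided
#' `p_primary` quantiles of the point-wise null form clusters (1D adjacency
#' for series, 4-connectivity for time-frequency maps) whose sizes are
#' compared with the permutation distribution of the maximal cluster size.
#'
#' @param maps `channel x time` matrix or `channel x freq x time` array of
#'   per-channel event-locked values (>= 8 channels).
#' @param n_perm permutations (default 1000).
#' @param p_primary point-wise primary threshold (default 0.05, two-sided).
#' @param p_cluster cluster-level threshold (default 0.05). With
#'   `p_cluster = 1` every suprathreshold point survives, i.e. the test
#'   reduces to the point-wise test.
#' @param seed optional integer seed.
#' @return An object of class `cluster_test_result`: list with `mask`
#'   (logical, significant after correction), `primary_mask`, `clusters`
#'   (data frame: id, size, p), `observed` (the across-channel mean),
#'   `n_perm`.
#' @export
cluster_signflip_test <- function(maps, n_perm = 1000L, p_primary = 0.05,
                                  p_cluster = 0.05, seed = NULL) {
  dm <- dim(maps)
  if (dm[1] < 8L) stop("need at least 8 channels", call. = FALSE)
  n_ch <- dm[1]
  flat <- matrix(maps, nrow = n_ch)      # channels x points
  obs <- colMeans(flat)
  ## independent per-channel flips: flipping exactly half the channels
  ## would constrain the flip sum to zero and shrink the null variance,
  ## making the point-wise test anticonservative
  run <- function() {
    null <- matrix(0, n_perm, length(obs))
    for (i in seq_len(n_perm)) {
      sgn <- sample(c(-1, 1), n_ch, replace = TRUE)
      null[i, ] <- colMeans(flat * sgn)
    }
    null
  }
  null <- if (is.null(seed)) run() else with_seed(seed, run())
  lo <- apply(null, 2, quantile, probs = p_primary / 2)
  hi <- apply(null, 2, quantile, probs = 1 - p_primary / 2)
  primary <- obs < lo | obs > hi
  shape <- if (length(dm) == 2L) dm[2] else dm[-1]
  cl_obs <- label_clusters(primary, shape)
  ## max-cluster null
  max_null <- vapply(seq_len(n_perm), function(i) {
    pm <- null[i, ] < lo | null[i, ] > hi
    cl <- label_clusters(pm, shape)
    if (nrow(cl$table) == 0L) 0L else max(cl$table$size)
  }, integer(1))
  mask <- rep(FALSE, length(obs))
  if (nrow(cl_obs$table) > 0L) {
    cl_obs$table$p <- vapply(cl_obs$table$size, function(s) {
      (1 + sum(max_null >= s)) / (n_perm + 1)
    }, numeric(1))
    for (k in seq_len(nrow(cl_obs$table))) {
      if (cl_obs$table$p[k] <= p_cluster) {
        mask[cl_obs$labels == cl_obs$table$id[k]] <- TRUE
      }
    }
  } else {
    cl_obs$table$p <- numeric(0)
  }
  dim(mask) <- shape
  dim(primary) <- shape
  dim(obs) <- shape
  structure(list(mask = mask, primary_mask = primary,
                 clusters = cl_obs$table, observed = obs, n_perm = n_perm),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf(
    "Cluster sign-flip test: %d cluster(s), %d significant point(s)\n",
    nrow(x$clusters), sum(x$mask)))
  invisible(x)
}

## Connected components of a logical vector (1D runs) or matrix
## (4-connectivity). Returns integer labels and a size table.
label_clusters <- function(flag, shape) {
  labels <- integer(length(flag))
  if (length(shape) == 1L) {
    r <- rle(as.vector(flag))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    id <- 0L
    for (i in which(r$values)) {
      id <- id + 1L
      labels[starts[i]:ends[i]] <- id
    }
  } else {
    m <- matrix(flag, shape[1], shape[2])
    lab <- matrix(0L, shape[1], shape[2])
    id <- 0L
    for (start in which(m)) {
      if (lab[start] != 0L) next
      id <- id + 1L
      stack <- start
      while (length(stack) > 0L) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (lab[cur] != 0L || !m[cur]) next
        lab[cur] <- id
        i <- (cur - 1L) %% shape[1] + 1L
        j <- (cur - 1L) %/% shape[1] + 1L
        if (i > 1L) stack <- c(stack, cur - 1L)
        if (i < shape[1]) stack <- c(stack, cur + 1L)
        if (j > 1L) stack <- c(stack, cur - shape[1])
        if (j < shape[2]) stack <- c(stack, cur + shape[1])
      }
    }
    labels <- as.vector(lab)
  }
  sizes <- tabulate(labels)
  list(labels = labels,
       table = data.frame(id = seq_along(sizes), size = sizes))
}

#' Peak-latency test of turn-locked activity
#'
#' Estimates, per channel, the latency of the maximum of the turn-locked
#' average within a window (ties broken toward the earlier latency), then
#' tests whether the group-mean latency differs from zero by sign-flipping
#' latencies within participant blocks. Channels with a flat average are
#' dropped with a warning.
#'
#' @param channel_averages `channel x lag` matrix of turn-locked averages.
#' @param lag_s lag axis in seconds.
#' @param participant participant of each channel.
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with `latency_s` (per channel), `mean_latency_s`, and `test`
#'   (a two-sided `permutation_result`).
#' @export
peak_latency_test <- function(channel_averages, lag_s, participant,
                              n_perm = 1000L, seed = NULL) {
  stopifnot(ncol(channel_averages) == length(lag_s))
  flat <- apply(channel_averages, 1, function(x) sd(x) < 1e-12)
  if (any(flat)) {
    warning(sum(flat), " flat channel(s) dropped from the latency test")
    channel_averages <- channel_averages[!flat, , drop = FALSE]
    participant <- participant[!flat]
  }
  lat <- apply(channel_averages, 1, function(x) lag_s[which.max(x)])
  test <- condition_difference_test(lat, rep(0, length(lat)), participant,
                                    n_perm = n_perm, seed = seed,
                                    alternative = "two.sided")
  list(latency_s = lat, mean_latency_s = mean(lat), test = test)
}

#' Behavioural cross-correlation and single-trial regression
#'
#' Relates band amplitude dynamics to behavioural variables two ways:
#' (1) per channel, the trial-averaged cross-correlation between amplitude
#' and each behavioural variable over lags up to `max_lag_s` (negative peak
#' lag = amplitude leads); (2) per trial and channel, an OLS regression of
#' amplitude on all behavioural variables jointly, with group-level
#' inference on the mean coefficients by sign-flip permutation within
#' participant blocks and max-statistic correction across variables.
#'
#' @param band `trial x time x channel` array on the common timeline.
#' @param behavior named list of `trial x time` matrices (e.g. speed,
#'   hip_yaw_vel, head_yaw_vel, est_phase), same timeline.
#' @param fs sampling rate (Hz).
#' @param participant participant of each channel.
#' @param max_lag_s maximal cross-correlation lag (default 2 s).
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with `lag_s`, `xcorr` (`variable x channel x lag` array),
#'   `coefficients` (`variable x channel` mean single-trial coefficients),
#'   `p` (per variable, max-statistic corrected), `dropped` (names of
#'   constant variables dropped with a warning).
#' @export
behavior_theta_analysis <- function(band, behavior, fs, participant,
                                    max_lag_s = 2, n_perm = 1000L,
                                    seed = NULL) {
  stopifnot(length(dim(band)) == 3L, length(behavior) >= 1L)
  n_tr <- dim(band)[1]
  nt <- dim(band)[2]
  n_ch <- dim(band)[3]
  dropped <- names(behavior)[vapply(behavior, function(b) {
    sd(as.vector(b)) < 1e-12
  }, logical(1))]
  if (length(dropped) > 0L) {
    warning("constant behavioural variable(s) dropped: ",
            paste(dropped, collapse = ", "))
    behavior <- behavior[setdiff(names(behavior), dropped)]
  }
  n_var <- length(behavior)
  max_lag <- round(max_lag_s * fs)
  lags <- -max_lag:max_lag

  xcorr <- array(0, dim = c(n_var, n_ch, length(lags)),
                 dimnames = list(names(behavior), NULL, NULL))
  for (v in seq_len(n_var)) {
    B <- behavior[[v]]
    for (cc in seq_len(n_ch)) {
      acc <- numeric(length(lags))
      for (tr in seq_len(n_tr)) {
        a <- band[tr, , cc]
        b <- B[tr, ]
        ## r(l) = cor(behaviour(t), amplitude(t + l)): a negative peak lag
        ## means the amplitude leads the behavioural variable
        acc <- acc + vapply(lags, function(l) {
          if (l >= 0) {
            ia <- 1:(nt - l); ib <- (1 + l):nt
          } else {
            ia <- (1 - l):nt; ib <- 1:(nt + l)
          }
          suppressWarnings(r <- cor(b[ia], a[ib]))
          if (is.na(r)) 0 else r
        }, numeric(1))
      }
      xcorr[v, cc, ] <- acc / n_tr
    }
  }

  ## single-trial joint regression, mean coefficient per channel
  coefs <- matrix(0, n_var, n_ch, dimnames = list(names(behavior), NULL))
  for (cc in seq_len(n_ch)) {
    cs <- matrix(0, n_tr, n_var)
    for (tr in seq_len(n_tr)) {
      Xb <- vapply(behavior, function(B) B[tr, ], numeric(nt))
      Xb <- scale(Xb)
      Xb[is.na(Xb)] <- 0
      w <- ols_solve(cbind(1, Xb), cbind(band[tr, , cc]))
      cs[tr, ] <- w[-1L, 1L]
    }
    coefs[, cc] <- colMeans(cs)
  }

  ## group test: sign-flip channel coefficients, max-|statistic| across
  ## variables for multiplicity correction
  obs <- rowMeans(coefs)
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      sgn <- sample(c(-1, 1), n_ch, replace = TRUE)
      max(abs(coefs %*% sgn) / n_ch)
    }, numeric(1))
  }
  null_max <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- vapply(abs(obs), function(o) {
    (1 + sum(null_max >= o)) / (n_perm + 1)
  }, numeric(1))

  list(lag_s = lags / fs, xcorr = xcorr, coefficients = coefs, p = p,
       dropped = dropped, participant = participant)
}

#' Root-mean-square deviation of a walked trajectory from the ideal route
#'
#' Perpendicular distance of each trajectory point to the nearest point of
#' the ideal route polyline, aggregated as an RMSE in metres. Used to
#' quantify route learning.
#'
#' @param traj a `trajectory` (or any data frame with `x`, `y`).
#' @param route a [route_template()].
#' @return RMSE in metres.
#' @export
route_rmse <- function(traj, route) {
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  P <- cbind(traj$x, traj$y)
  V <- route$vertices
  d2 <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(V) - 1L)) {
    a <- V[s, ]
    b <- V[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dx <- P[, 1] - (a[1] + tt * ab[1])
    dy <- P[, 2] - (a[2] + tt * ab[2])
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(mean(d2))
}
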