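#' Simulate a walking trajectory along a route
#'
#' Integrates a walking-speed profile along the route polyline at the motion
#' sampling rate. Speed dips smoothly as the walker approaches each turn
#' (deceleration begins within ~1 s of the turn), lateral jitter is added
#' perpendicular to the path, and hip/head yaw follow the path heading with
#' yaw changes concentrated at turns. All motion signals are smoothed with a
#' Gaussian window (`cfg$smooth_window_s`, default 0.2 s).
#'
#' @param route a [route_template()].
#' @param cfg a [synth_config()].
#' @param trial_seed integer seed; the trajectory is deterministic for a
#'   fixed seed.
#' @param jitter lateral jitter SD in metres; defaults to
#'   `cfg$traj_jitter_sd`. With `jitter = 0` the trajectory lies exactly on
#'   the ideal polyline.
#' @return An object of class `trajectory`: a data frame with columns `t`
#'   (s), `x`, `y` (m), `hip_yaw`, `head_yaw` (deg), `speed` (m/s), with
#'   attributes `turn_times` (s, one per turn) and `arclength` (m per
#'   sample).
#' @export
simulate_trajectory <- function(route, cfg = synth_config(), trial_seed = 1L,
                                jitter = cfg$traj_jitter_sd) {
  stopifnot(inherits(route, "route_template"))
  fs <- cfg$fs_motion
  dt <- 1 / fs
  cl <- route_cumlen(route)
  total_len <- cl[length(cl)]
  turn_s <- cl[2:(length(cl) - 1L)]

  with_seed(trial_seed, {
    v_base <- cfg$speed_base * runif(1, 0.92, 1.08)
    ## spatial speed profile: smooth dips centred on each turn
    dip_width <- 0.55 * v_base            # metres; deceleration ~1 s around turn
    speed_at <- function(s) {
      dip <- rep(0, length(s))
      for (ts in turn_s) dip <- dip + exp(-0.5 * ((s - ts) / dip_width)^2)
      v_base * (1 - 0.4 * pmin(dip, 1))
    }
    ## integrate ds/dt = v(s)
    s <- numeric(ceiling(3 * total_len / v_base * fs))
    n <- 1L
    while (s[n] < total_len) {
      s[n + 1L] <- s[n] + dt * speed_at(s[n])
      n <- n + 1L
    }
    s <- s[seq_len(n)]
    s[n] <- total_len
    t <- (seq_len(n) - 1L) * dt

    xy <- route_point(route, s)
    if (jitter > 0) {
      seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE),
                  route$n_segments)
      ## normal direction varies smoothly through turns so that the offset
      ## does not jump (and create spurious speed spikes) at a corner
      head_ang <- gauss_smooth(route$headings[seg], fs, 0.5)
      lat <- gauss_smooth(rnorm(n, 0, jitter * 3), fs, 0.5)
      lat <- gauss_smooth(lat, fs, cfg$smooth_window_s)
      lat <- lat / max(stats::sd(lat), 1e-12) * jitter
      xy <- xy + cbind(-sin(head_ang), cos(head_ang)) * lat
    }

    ## turn times: arc-length crossings of the segment boundaries
    turn_times <- vapply(turn_s, function(ts) {
      i <- which(s >= ts)[1L]
      if (i == 1L) return(t[1L])
      t[i - 1L] + dt * (ts - s[i - 1L]) / max(s[i] - s[i - 1L], 1e-12)
    }, numeric(1))

    seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE), route$n_segments)
    heading_deg <- route$headings[seg] * 180 / pi
    hip_yaw <- gauss_smooth(heading_deg + rnorm(n, 0, 2), fs, 0.3)
    head_yaw <- gauss_smooth(heading_deg + rnorm(n, 0, 3), fs, 0.3)

    step <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2) * fs
    speed <- gauss_smooth(c(step[1], step), fs, cfg$smooth_window_s)
  })

  out <- data.frame(t = t, x = xy[, 1], y = xy[, 2],
                    hip_yaw = hip_yaw, head_yaw = head_yaw, speed = speed)
  attr(out, "turn_times") <- turn_times
  attr(out, "arclength") <- s
  attr(out, "fs") <- fs
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Turn anchor times of a trajectory
#'
#' @param traj a `trajectory`.
#' @return numeric vector: trial start, turn times, trial end (seconds).
#' @export
trajectory_anchors <- function(traj) {
  c(traj$t[1], attr(traj, "turn_times"), traj$t[nrow(traj)])
}
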