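#' Write / read a session bundle on disk
#'
#' The native on-disk format is a documented flat binary array for the
#' signals (float64, little endian, channel index fastest) with a JSON
#' sidecar header (sampling rate, dimensions, channel labels), plus CSV
#' tables for trials, channels, trajectories, turn times and ground-truth
#' interval lists, and a JSON description of the route. Time conventions:
#' seconds, 0-based sample times, half-open intervals `[start, stop)`.
#'
#' @param session a `session_bundle`.
#' @param dir output directory (created if missing).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns the reconstructed `session_bundle` (ground-truth bout/IED
#'   intervals and trial tables round-trip; generator config does not).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "signals.bin"), "wb")
  writeBin(as.vector(session$signals), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(fs = session$fs, n_channels = nrow(session$signals),
         n_samples = ncol(session$signals), dtype = "float64",
         byte_order = "little", order = "channel_fastest",
         channels = session$channels$channel),
    file.path(dir, "signals.json"), auto_unbox = TRUE, digits = NA)
  write.csv(session$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(session$channels, file.path(dir, "channels.csv"),
            row.names = FALSE)
  traj <- do.call(rbind, lapply(seq_along(session$trajectories), function(i) {
    cbind(trial = i, as.data.frame(session$trajectories[[i]]))
  }))
  write.csv(traj, file.path(dir, "trajectories.csv"), row.names = FALSE)
  turns <- do.call(rbind, lapply(seq_along(session$trajectories), function(i) {
    tt <- attr(session$trajectories[[i]], "turn_times")
    data.frame(trial = i, turn = seq_along(tt), time_s = tt)
  }))
  write.csv(turns, file.path(dir, "turns.csv"), row.names = FALSE)
  write.csv(session$ground_truth$bouts, file.path(dir, "gt_bouts.csv"),
            row.names = FALSE)
  write.csv(session$ground_truth$ied, file.path(dir, "gt_ied.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(vertices = session$route$vertices,
         segment_lengths = session$route$segment_lengths,
         turn_angles_deg = session$route$turn_angles_deg,
         n_turns = session$route$n_turns,
         handedness = session$route$handedness,
         fs_motion = attr(session$trajectories[[1]], "fs")),
    file.path(dir, "route.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "signals.json"),
                             simplifyVector = TRUE)
  con <- file(file.path(dir, "signals.bin"), "rb")
  x <- readBin(con, "double", n = hdr$n_channels * hdr$n_samples, size = 8,
               endian = "little")
  close(con)
  signals <- matrix(x, hdr$n_channels, hdr$n_samples)
  trials <- read.csv(file.path(dir, "trials.csv"),
                     stringsAsFactors = FALSE)
  bad <- which(trials$stop_s <= trials$start_s)
  if (length(bad) > 0L) {
    stop("trials.csv: stop_s <= start_s in row ", bad[1L], call. = FALSE)
  }
  channels <- read.csv(file.path(dir, "channels.csv"),
                       stringsAsFactors = FALSE)
  rj <- jsonlite::read_json(file.path(dir, "route.json"),
                            simplifyVector = TRUE)
  route <- structure(
    list(vertices = matrix(unlist(rj$vertices), ncol = 2),
         segment_lengths = rj$segment_lengths,
         turn_angles_deg = rj$turn_angles_deg, n_turns = rj$n_turns,
         n_segments = rj$n_turns + 1L, handedness = rj$handedness,
         headings = c(0, cumsum(rj$turn_angles_deg * pi / 180))),
    class = "route_template")
  traj_df <- read.csv(file.path(dir, "trajectories.csv"),
                      stringsAsFactors = FALSE)
  turns_df <- read.csv(file.path(dir, "turns.csv"), stringsAsFactors = FALSE)
  trajectories <- lapply(sort(unique(traj_df$trial)), function(i) {
    tr <- traj_df[traj_df$trial == i, -1L]
    rownames(tr) <- NULL
    attr(tr, "turn_times") <- turns_df$time_s[turns_df$trial == i]
    attr(tr, "fs") <- rj$fs_motion
    class(tr) <- c("trajectory", "data.frame")
    tr
  })
  gt_bouts <- read.csv(file.path(dir, "gt_bouts.csv"),
                       stringsAsFactors = FALSE)
  gt_ied <- read.csv(file.path(dir, "gt_ied.csv"), stringsAsFactors = FALSE)
  structure(list(signals = signals, fs = hdr$fs, channels = channels,
                 trials = trials, trajectories = trajectories,
                 ground_truth = list(bouts = gt_bouts, ied = gt_ied,
                                     anchors = NULL),
                 route = route, cfg = NULL),
            class = "session_bundle")
}

#' File-based pipeline driver
#'
#' Reads a session from `session_dir` (native format, see
#' [write_session()]), runs [run_navigation_pipeline()] and writes tidy CSV
#' results plus a machine-readable JSON log (stage list, parameters, seed)
#' to `out_dir`. Outputs are deterministic for a fixed seed.
#'
#' @param config_path optional flat `key = value` text file overriding
#'   [pipeline_config()] fields (numeric values; `f_range` as
#'   `f_lo`/`f_hi`).
#' @param session_dir directory holding the session.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the [run_navigation_pipeline()] result.
#' @export
run_pipeline <- function(config_path = NULL, session_dir, out_dir,
                         seed = 1L) {
  cfg_args <- list(f_range = c(1, 30))
  if (!is.null(config_path)) {
    kv <- read_flat_config(config_path)
    if (!is.null(kv$f_lo) || !is.null(kv$f_hi)) {
      cfg_args$f_range <- c(kv$f_lo %||% 1, kv$f_hi %||% 30)
      kv$f_lo <- kv$f_hi <- NULL
    }
    keep <- intersect(names(kv), names(formals(pipeline_config)))
    cfg_args[keep] <- kv[keep]
  }
  config <- do.call(pipeline_config, cfg_args)
  session <- read_session(session_dir)
  res <- run_navigation_pipeline(session, config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$consistency$consistency,
            file.path(out_dir, "consistency.csv"), row.names = FALSE)
  write.csv(res$proc$bouts$intervals, file.path(out_dir, "bouts.csv"),
            row.names = FALSE)
  write.csv(res$proc$mask$intervals, file.path(out_dir, "ied_intervals.csv"),
            row.names = FALSE)
  write.csv(data.frame(mid_deg = res$decode$imag$report$hist$mid_deg,
                       real = res$decode$real$hist$prop,
                       imagined = res$decode$imag$report$hist$prop,
                       control = res$decode$ctrl$report$hist$prop),
            file.path(out_dir, "error_histograms.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stages = c("artifacts", "spectral", "bouts", "warp",
                    "consistency", "decode", "stats"),
         seed = seed, config = unclass(config),
         real_mean_abs_err_deg = res$decode$real$mean_abs_err_deg,
         imag_mean_abs_err_deg = res$decode$imag$report$mean_abs_err_deg,
         ctrl_mean_abs_err_deg = res$decode$ctrl$report$mean_abs_err_deg),
    file.path(out_dir, "log.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Minimal European Data Format (EDF) importer
#'
#' Reads continuous signals from an EDF file into the `channel x sample`
#' matrix the pipeline expects, applying the per-channel digital-to-physical
#' scaling from the header. Supports plain EDF (not EDF+ annotations or
#' discontinuous files); all channels must share one sampling rate.
#'
#' @param path EDF file.
#' @return list with `signals` (`channel x sample`), `fs` (Hz), `labels`,
#'   `start` (header start date/time string).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field != 0)",
                           call. = FALSE)
  rd(80); rd(80)                         # patient / recording id
  start <- paste(rd(8), rd(8))
  header_bytes <- as.integer(rd(8))
  rd(44)                                 # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))  # transducer
  vapply(seq_len(ns), function(i) rd(8), character(1))   # unit
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), character(1))  # prefilter
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), character(1))  # reserved
  seek(con, header_bytes)
  if (length(unique(nsamp)) != 1L) {
    stop("channels with mixed sampling rates are not supported",
         call. = FALSE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  signals <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = nsamp[ch], size = 2,
                   endian = "little", signed = TRUE)
      signals[ch, (r - 1L) * nsamp[1] + seq_len(nsamp[1])] <-
        gain[ch] * d + offset[ch]
    }
  }
  list(signals = signals, fs = nsamp[1] / rec_dur, labels = labels,
       start = start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) next
    val <- trimws(parts[2L])
    num <- suppressWarnings(as.numeric(val))
    kv[[trimws(parts[1L])]] <- if (is.na(num)) val else num
  }
  kv
}
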