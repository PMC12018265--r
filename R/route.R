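#' Construct an abstract route template
#'
#' A navigational route is an ordered polyline of linear segments connected
#' by turns, walked inside a motion-capture room. The default geometry has
#' four turns joining five segments; a participant-specific variant with an
#' extra turn is obtained by raising `n_turns`.
#'
#' @param n_turns integer number of turns (>= 1); the route has
#'   `n_turns + 1` segments.
#' @param handedness `"left"` or `"right"`: direction of the first turn.
#' @param seed integer seed controlling segment lengths and turn angles;
#'   the template is deterministic for a fixed seed.
#' @param segment_lengths optional numeric vector of segment lengths in
#'   metres (length `n_turns + 1`); drawn uniformly from 2.4-3.4 m when
#'   omitted.
#' @return An object of class `route_template` with fields `vertices`
#'   (`(n_segments + 1) x 2` matrix, metres), `segment_lengths`,
#'   `turn_angles_deg`, `n_turns`, `n_segments` and `handedness`.
#' @examples
#' rt <- route_template(4, "left", seed = 7)
#' rt$n_segments  # 5
#' @export
route_template <- function(n_turns = 4L, handedness = c("left", "right"),
                           seed = 1L, segment_lengths = NULL) {
  handedness <- match.arg(handedness)
  if (!is.numeric(n_turns) || length(n_turns) != 1L || n_turns < 1 ||
      n_turns != round(n_turns)) {
    stop("`n_turns` must be a single integer >= 1", call. = FALSE)
  }
  n_turns <- as.integer(n_turns)
  n_seg <- n_turns + 1L
  with_seed(seed, {
    if (is.null(segment_lengths)) {
      segment_lengths <- runif(n_seg, 2.4, 3.4)
    }
    if (length(segment_lengths) != n_seg || any(segment_lengths <= 0)) {
      stop("`segment_lengths` must be ", n_seg, " positive values",
           call. = FALSE)
    }
    sign0 <- if (handedness == "left") 1 else -1
    signs <- sign0 * rep_len(c(1, -1), n_turns)
    turn_angles <- signs * runif(n_turns, 60, 110)
  })
  heading <- c(0, cumsum(turn_angles * pi / 180))
  verts <- matrix(0, n_seg + 1L, 2L)
  for (i in seq_len(n_seg)) {
    verts[i + 1L, ] <- verts[i, ] +
      segment_lengths[i] * c(cos(heading[i]), sin(heading[i]))
  }
  structure(
    list(vertices = verts, segment_lengths = segment_lengths,
         turn_angles_deg = turn_angles, n_turns = n_turns,
         n_segments = n_seg, handedness = handedness,
         headings = heading),
    class = "route_template")
}

#' @export
print.route_template <- function(x, ...) {
  cat("Route template:", x$n_segments, "segments /", x$n_turns, "turns,",
      x$handedness, "handed\n")
  cat("  segment lengths (m):",
      paste(sprintf("%.2f", x$segment_lengths), collapse = ", "), "\n")
  invisible(x)
}

## Cumulative arc length at each vertex (0 at the start).
route_cumlen <- function(route) c(0, cumsum(route$segment_lengths))

## Point(s) on the ideal polyline at arc length s (clamped to the route).
route_point <- function(route, s) {
  cl <- route_cumlen(route)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE), route$n_segments)
  frac <- (s - cl[seg]) / route$segment_lengths[seg]
  p0 <- route$vertices[seg, , drop = FALSE]
  p1 <- route$vertices[seg + 1L, , drop = FALSE]
  p0 + frac * (p1 - p0)
}

## Relative segment phase for arc lengths s: 0 at segment entry, 2*pi at the
## turn ending the segment (wrapped to [0, 2*pi)). Also returns segment index.
route_phase <- function(route, s) {
  cl <- route_cumlen(route)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE), route$n_segments)
  frac <- (s - cl[seg]) / route$segment_lengths[seg]
  list(phi = wrap_phase(2 * pi * frac), segment = seg)
}
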