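#' Circular-variable helpers
#'
#' Relative position within a route segment is modelled as an angle on the
#' unit circle: 0 at segment entry, advancing to 2*pi at the turn that ends
#' the segment. These helpers wrap angles, compute circular means and the
#' mean resultant length used to score reconstruction accuracy.
#'
#' @param x numeric vector of angles in radians.
#' @return `wrap_angle()` maps to (-pi, pi]; `wrap_phase()` maps to [0, 2*pi);
#'   `circ_mean()` returns the circular mean in (-pi, pi]; `resultant_length()`
#'   the mean resultant length in [0, 1].
#' @examples
#' wrap_angle(3 * pi / 2)   # -pi/2
#' resultant_length(rep(1, 5))  # 1
#' @name circular
NULL

#' @rdname circular
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  i <- which(w > pi)
  w[i] <- w[i] - 2 * pi
  w
}

#' @rdname circular
#' @export
wrap_phase <- function(x) x %% (2 * pi)

#' @rdname circular
#' @export
circ_mean <- function(x) {
  x <- x[is.finite(x)]
  atan2(mean(sin(x)), mean(cos(x)))
}

#' @rdname circular
#' @export
resultant_length <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

## Squared circular distance used as the DTW local cost for phase alignment.
circ_dist2 <- function(a, b) wrap_angle(a - b)^2
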