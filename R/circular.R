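#' Wrap angles into the interval [0, 2*pi)
#'
#' @param x numeric vector or matrix of angles in radians.
#' @return `x` reduced modulo `2*pi` into `[0, 2*pi)`.
#' @export
#' @examples
#' wrap_phase(5 * pi / 2)  # pi/2
wrap_phase <- function(x) {
  x %% (2 * pi)
}

#' Circular distance between angles
#'
#' Shortest angular separation, `min(|a-b|, 2*pi - |a-b|)`, always in
#' `[0, pi]`.
#'
#' @param a,b angles in radians (vectors or matrices, recycled).
#' @return non-negative distances.
#' @export
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Minimal signed circular difference
#'
#' Signed difference `a - b` reduced to the principal interval `(-pi, pi]`.
#' Positive values mean `a` leads `b`.
#'
#' @param a,b angles in radians.
#' @return signed differences in `(-pi, pi]`.
#' @export
circ_signed_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d - ifelse(d > pi, 2 * pi, 0)
}
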