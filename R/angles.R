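# Circular helpers shared by every stage.  All internal angles are radians in
# mathematical convention (0 = +x axis, counterclockwise positive), wrapped to
# [0, 2*pi).

#' Wrap angles to [0, 2*pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  # %% can return 2*pi for tiny negative inputs because of rounding
  out[out >= 2 * pi] <- 0
  out
}

#' Signed smallest angular difference
#'
#' Returns the signed difference `a - b` mapped to `(-pi, pi]`, i.e. the
#' shortest rotation taking `b` onto `a`.
#'
#' @param a,b angles in radians.
#' @return signed difference in `(-pi, pi]`.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Circular mean of a set of angles
#'
#' The direction of the summed unit vectors.  Undefined (returns `NA` with a
#' warning suppressed by `na_ok`) when the resultant length is numerically
#' zero, e.g. for an antipodal pair: zero-filling such cases would bias
#' aggregates toward 0.
#'
#' @param angles_rad non-empty numeric vector of angles in radians.
#' @param na.rm drop `NA` values first.
#' @return circular mean in `[0, 2*pi)`, or `NA_real_` when the resultant
#'   length is below `1e-12` (mean direction undefined).
#' @export
circular_mean <- function(angles_rad, na.rm = FALSE) {
  if (na.rm) angles_rad <- angles_rad[!is.na(angles_rad)]
  if (length(angles_rad) == 0L) stop("circular_mean: empty angle set")
  s <- sum(sin(angles_rad))
  c_ <- sum(cos(angles_rad))
  if (sqrt(s^2 + c_^2) / length(angles_rad) < 1e-12) return(NA_real_)
  wrap_angle(atan2(s, c_))
}

#' Mean resultant length
#'
#' Length of the average unit vector of a set of angles, in `[0, 1]`.
#' Applied to the headings of all group members this is the polar order
#' parameter: 1 when everyone points the same way, 0 for exactly balanced
#' (e.g. antipodal) headings.
#'
#' @inheritParams circular_mean
#' @return scalar in `[0, 1]`.
#' @export
resultant_length <- function(angles_rad, na.rm = FALSE) {
  if (na.rm) angles_rad <- angles_rad[!is.na(angles_rad)]
  n <- length(angles_rad)
  if (n == 0L) stop("resultant_length: empty angle set")
  r <- sqrt(sum(cos(angles_rad))^2 + sum(sin(angles_rad))^2) / n
  min(r, 1)
}

#' Unwrap a heading series
#'
#' Removes 2*pi discontinuities so that consecutive samples differ by the
#' signed shortest-arc step; linear statistics (Pearson correlation,
#' change-point costs) then behave sensibly on headings.
#'
#' @param theta heading series in radians; `NA`s are carried through.
#' @return cumulative (unwrapped) series, same length.
#' @export
unwrap_angle <- function(theta) {
  n <- length(theta)
  if (n <= 1L) return(theta)
  ok <- !is.na(theta)
  idx <- which(ok)
  if (length(idx) <= 1L) return(theta)
  out <- theta
  vals <- theta[idx]
  steps <- angle_diff(vals[-1L], vals[-length(vals)])
  out[idx] <- c(vals[1L], vals[1L] + cumsum(steps))
  out
}

#' Sliding circular variance
#'
#' Circular variance (1 - mean resultant length) of a heading series in a
#' centred sliding window; used as the "directedness" series for
#' change-point detection.
#'
#' @param theta heading series in radians.
#' @param window window width in samples (odd values centre exactly).
#' @return series of the same length; ends use the truncated window.
#' @export
sliding_circular_variance <- function(theta, window = 15L) {
  n <- length(theta)
  if (window < 2L) stop("sliding_circular_variance: window must be >= 2")
  half <- window %/% 2L
  cs <- cumsum(ifelse(is.na(theta), 0, cos(theta)))
  ss <- cumsum(ifelse(is.na(theta), 0, sin(theta)))
  cnt <- cumsum(!is.na(theta))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  csum <- cs[hi] - ifelse(lo > 1L, cs[lo - 1L], 0)
  ssum <- ss[hi] - ifelse(lo > 1L, ss[lo - 1L], 0)
  m <- cnt[hi] - ifelse(lo > 1L, cnt[lo - 1L], 0)
  out <- rep(NA_real_, n)
  pos <- m > 0L
  out[pos] <- 1 - sqrt(csum[pos]^2 + ssum[pos]^2) / m[pos]
  out
}

#' Rotate an angle toward a target with a capped turn
#'
#' Shortest-arc rotation of `current` toward `target`, with the magnitude of
#' the turn clamped at `max_turn` radians (one time step's worth of turning).
#'
#' @param current,target angles in radians (vectorised).
#' @param max_turn maximum turn magnitude per call, radians.
#' @return new angle(s) in `[0, 2*pi)`.
#' @export
turn_toward <- function(current, target, max_turn) {
  if (any(max_turn < 0)) stop("turn_toward: max_turn must be >= 0")
  d <- angle_diff(target, current)
  step <- pmin(abs(d), max_turn) * sign(d)
  wrap_angle(current + step)
}

#' Circular (angular-angular) correlation
#'
#' Fisher-Lee circular correlation between two angle vectors; used to check
#' that departure and destination directions agree across events.
#'
#' @param a,b angle vectors in radians, equal length.
#' @return correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("circular_correlation: need >= 2 complete pairs")
  num <- sum(sin(outer(a, a, "-")) * sin(outer(b, b, "-")))
  den <- sqrt(sum(sin(outer(a, a, "-"))^2) * sum(sin(outer(b, b, "-"))^2))
  if (den == 0) return(NA_real_)
  num / den
}
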