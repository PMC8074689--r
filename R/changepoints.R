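# Penalized exact change-point segmentation (PELT-style pruned dynamic
# programming).  Two cost families: squared error around a segment mean
# ("mean") and Gaussian likelihood with segment mean and variance
# ("mean_and_variance").  Used on group speed, unwrapped group heading and
# sliding heading variance to demarcate collective departures.

# Segment cost closures over cumulative sums; a..b inclusive, 1-based.
.cost_mean <- function(x) {
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  function(a, b) {
    m <- b - a + 1
    (s2[b + 1] - s2[a]) - (s1[b + 1] - s1[a])^2 / m
  }
}

.cost_meanvar <- function(x, var_floor = 1e-8) {
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  function(a, b) {
    m <- b - a + 1
    v <- pmax((s2[b + 1] - s2[a]) / m - ((s1[b + 1] - s1[a]) / m)^2, var_floor)
    m * (log(2 * pi * v) + 1)
  }
}

# Robust noise-scale estimate from first differences (a step change inflates
# the raw sd, not the difference MAD).
.noise_sd <- function(x) {
  d <- diff(x)
  s <- stats::median(abs(d - stats::median(d))) / 0.6744898
  s / sqrt(2)
}

#' Detect change-points in a numeric series
#'
#' Exact minimization of `sum(segment costs) + penalty * (#change-points)`
#' with PELT pruning.  For `target = "mean"` the segment cost is the squared
#' error around the segment mean and the automatic penalty is
#' `3 * sigma^2 * log(n)` with `sigma` estimated robustly from first
#' differences; for `"mean_and_variance"` the cost is the Gaussian
#' log-likelihood with per-segment mean and variance and the automatic
#' penalty is `3 * log(n)`.
#'
#' @param series numeric vector, length >= 10, all finite.
#' @param target `"mean"` or `"mean_and_variance"`.
#' @param penalty positive penalty; `NULL` for the automatic default above.
#' @param times_s optional time axis (same length); reported change-point
#'   times are taken from it.  Defaults to indices `1..n`.
#' @param min_seg minimum segment length (default 2).
#' @param series_name label carried into the result.
#' @return a `changepoint_set` list: `series_name`, `times_s` (time of the
#'   first sample of each new regime, strictly increasing), `strengths`
#'   (cost reduction of each split against merging its two segments),
#'   `penalty`, `n`.
#' @export
detect_changepoints <- function(series, target = c("mean", "mean_and_variance"),
                                penalty = NULL, times_s = NULL,
                                min_seg = 2L, series_name = "series") {
  target <- match.arg(target)
  x <- as.numeric(series)
  n <- length(x)
  if (n < 10L) stop("detect_changepoints: series length must be >= 10")
  if (any(!is.finite(x))) stop("detect_changepoints: non-finite values in series")
  if (!is.null(penalty) && penalty <= 0) {
    stop("detect_changepoints: penalty must be > 0")
  }
  if (is.null(times_s)) times_s <- seq_len(n)
  if (length(times_s) != n) stop("detect_changepoints: times_s length mismatch")

  if (is.null(penalty)) {
    penalty <- if (target == "mean") {
      s2 <- max(.noise_sd(x)^2, 1e-12)
      3 * s2 * log(n)
    } else {
      3 * log(n)
    }
  }
  cost <- if (target == "mean") .cost_mean(x) else .cost_meanvar(x)

  # PELT over last-change candidates tau in {0, min_seg, ..., t - min_seg}
  Fv <- c(-penalty, rep(Inf, n))          # Fv[tau + 1] = optimal cost of x[1..tau]
  prev <- rep(0L, n + 1L)
  cand <- 0L
  for (t in seq_len(n)) {
    ok <- cand <= t - min_seg
    if (any(ok)) {
      taus <- cand[ok]
      costs <- vapply(taus, function(a) cost(a + 1L, t), 0)
      vals <- Fv[taus + 1L] + costs + penalty
      j <- which.min(vals)
      Fv[t + 1L] <- vals[j]
      prev[t + 1L] <- taus[j]
      # prune: tau stays viable only if it could still win later; recent
      # candidates (inside min_seg) are carried forward untouched
      keep <- Fv[taus + 1L] + costs <= Fv[t + 1L]
      cand <- c(taus[keep], cand[!ok], t)
    } else {
      cand <- c(cand, t)
    }
  }

  cps <- integer(0)
  tau <- n
  while (tau > 0L) {
    p <- prev[tau + 1L]
    if (p > 0L) cps <- c(p, cps)
    tau <- p
  }
  # cps are the last indices of the closing segments; new regime starts at cp+1
  strengths <- numeric(length(cps))
  if (length(cps)) {
    bounds <- c(0L, cps, n)
    for (i in seq_along(cps)) {
      a <- bounds[i] + 1L; b <- bounds[i + 2L]; m <- cps[i]
      strengths[i] <- cost(a, b) - (cost(a, m) + cost(m + 1L, b))
    }
  }
  structure(list(series_name = series_name,
                 times_s = times_s[cps + 1L],
                 index = cps + 1L,
                 strengths = strengths,
                 penalty = penalty, n = n),
            class = "changepoint_set")
}
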