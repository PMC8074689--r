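# The central statistics: the decision parameter, its cross-correlation
# with group speed, the max-time-lag (CorrMax) and symmetry-index (Sym)
# summaries, bootstrap CIs on medians, and the one-sample t-test.

#' Decision parameter
#'
#' Mean resultant length of two unit vectors: the group mean heading and a
#' reference (departure or destination) direction:
#' the norm of `((cos a1 + cos a2)/2, (sin a1 + sin a2)/2)`,
#' which equals `|cos((a1 - a2)/2)|`: 1 when the group points at the
#' reference, 0 when it points the opposite way.  Vectorised; `NA` group
#' headings (undefined circular mean) give `NA`.
#'
#' @param group_mean_heading,reference_direction angles in radians.
#' @return r in `[0, 1]`.
#' @export
decision_parameter <- function(group_mean_heading, reference_direction) {
  sqrt(((cos(group_mean_heading) + cos(reference_direction)) / 2)^2 +
         ((sin(group_mean_heading) + sin(reference_direction)) / 2)^2)
}

#' Decision-parameter curve of an event
#'
#' Per-second decision parameter, group mean speed and polar order over the
#' event window (`window_pre_s` before to `window_post_s` after the
#' departure), against the departure direction (default) or the
#' destination direction.  Windows truncated by the data edge are flagged.
#'
#' @param event a retained `decision_event`.
#' @param group the [group_series()].
#' @param mode `"departure"` or `"destination"`.
#' @param config a [run_config()].
#' @return a `decision_curve` data.frame `rel_time_s, time_s, r, speed_mps,
#'   polar_order` with attributes `event_id`, `reference_mode`,
#'   `reference_direction_rad`, `truncated`.
#' @export
decision_curve <- function(event, group, mode = c("departure", "destination"),
                           config = run_config()) {
  mode <- match.arg(mode)
  ref <- switch(mode,
                departure = event$departure_direction_rad,
                destination = event$destination_direction_rad)
  if (!is.finite(ref)) stop("decision_curve: reference direction undefined")
  day <- group[group$day_id == event$day_id, , drop = FALSE]
  rel <- seq.int(-config$window_pre_s, config$window_post_s)
  want <- event$t_departure_s + rel
  ix <- match(want, day$time_s)
  truncated <- anyNA(ix)
  keep <- !is.na(ix)
  out <- data.frame(
    rel_time_s = rel[keep],
    time_s = want[keep],
    r = decision_parameter(day$mean_heading_rad[ix[keep]], ref),
    speed_mps = day$mean_speed_mps[ix[keep]],
    polar_order = day$polar_order[ix[keep]]
  )
  attr(out, "event_id") <- event$event_id
  attr(out, "reference_mode") <- mode
  attr(out, "reference_direction_rad") <- ref
  attr(out, "truncated") <- truncated
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' Cross-correlate a decision curve with group speed
#'
#' Classic sample cross-correlation (the base-statistics `ccf` convention):
#' both series are demeaned over the full window and normalised by the
#' full-window standard deviations; `corr[k] = cor(r(t + k), speed(t))`, so
#' a negative `CorrMax` lag means decision-parameter changes precede speed
#' changes (the voting signature).  `CorrMax` ties are broken toward the
#' smallest `|lag|`, then toward the negative lag.
#'
#' @param curve a [decision_curve()], or any data.frame with columns `r`
#'   and `speed_mps`.
#' @param max_lag_s maximum lag in seconds; `NULL` (default) uses the
#'   base-statistics ccf convention `10 * log10(n)` (about 23 s for the
#'   standard 201-step window).
#' @param clamp if `TRUE` (default) shrink the lag range so the window
#'   supports it (`n >= 2*L + 10`); if `FALSE`, violate that and get an
#'   error.  Truncated event windows need the clamp.
#' @return a `crosscorr_stats` list: `lags_s`, `corr`, `corr_max_lag_s`,
#'   `corr_max`, `symmetry_index`, `n`.
#' @export
cross_correlate <- function(curve, max_lag_s = NULL, clamp = TRUE) {
  x <- curve$r
  y <- curve$speed_mps
  ok <- is.finite(x) & is.finite(y)
  n <- length(x)
  if (is.null(max_lag_s)) max_lag_s <- floor(10 * log10(n))
  L <- as.integer(max_lag_s)
  if (clamp) L <- max(1L, min(L, (n - 10L) %/% 2L))
  if (n < 2L * L + 10L) {
    stop("cross_correlate: need >= 2*max_lag + 10 steps (have ", n, ")")
  }
  mx <- mean(x[ok]); my <- mean(y[ok])
  sx <- sqrt(mean((x[ok] - mx)^2)); sy <- sqrt(mean((y[ok] - my)^2))
  if (sx == 0 || sy == 0) stop("cross_correlate: zero-variance series")
  xc <- ifelse(ok, x - mx, 0)
  yc <- ifelse(ok, y - my, 0)
  lags <- seq.int(-L, L)
  corr <- vapply(lags, function(k) {
    if (k >= 0) sum(xc[(1 + k):n] * yc[1:(n - k)]) else
      sum(xc[1:(n + k)] * yc[(1 - k):n])
  }, 0) / (n * sx * sy)
  # max with deterministic tie-breaks: smallest |lag|, then negative sign
  best <- which(corr >= max(corr) - 1e-12)
  bl <- lags[best]
  bl <- bl[order(abs(bl), bl)]
  cml <- bl[1L]
  structure(list(lags_s = lags, corr = corr,
                 corr_max_lag_s = cml,
                 corr_max = corr[match(cml, lags)],
                 symmetry_index = .sym_from(lags, corr),
                 n = n),
            class = "crosscorr_stats")
}

.sym_from <- function(lags, corr) {
  sum(corr[lags > 0]) - sum(corr[lags < 0])
}

#' Symmetry index of a cross-correlation curve
#'
#' Area of the curve right of zero lag minus area left of zero (unit lag
#' spacing; lag 0 belongs to neither side).  Negative values indicate
#' anticipatory (voting-like) structure.
#'
#' @param stats a `crosscorr_stats`, or a list with `lags_s` and `corr`.
#' @return scalar symmetry index.
#' @export
symmetry_index <- function(stats) {
  lags <- stats$lags_s
  if (!setequal(lags, -lags)) {
    stop("symmetry_index: lag range must be symmetric about 0")
  }
  .sym_from(lags, stats$corr)
}

#' Bootstrap confidence interval for a pooled median
#'
#' Percentile CI (2.5%, 97.5%) of medians of resamples drawn with
#' replacement; deterministic under a fixed seed.
#'
#' @param values per-event statistics (>= 2 values).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed (the caller's RNG stream is untouched).
#' @return list `median`, `ci` (length 2), `n`, `n_boot`.
#' @export
pooled_bootstrap <- function(values, n_boot = 1000L, seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("pooled_bootstrap: need >= 2 values")
  if (n_boot < 1L) stop("pooled_bootstrap: n_boot must be >= 1")
  meds <- with_rng(seed, {
    m <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      m[b] <- stats::median(sample(values, replace = TRUE))
    }
    m
  })
  list(median = stats::median(values),
       ci = unname(stats::quantile(meds, c(0.025, 0.975))),
       n = length(values), n_boot = n_boot)
}

#' One-sample t-test
#'
#' @param values numeric, n >= 2, non-zero variance.
#' @param mu0 null mean.
#' @return list `t`, `df`, `p` (two-sided), `mean`.
#' @export
one_sample_t <- function(values, mu0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("one_sample_t: need >= 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("one_sample_t: zero variance")
  tstat <- (mean(values) - mu0) / (s / sqrt(n))
  df <- n - 1L
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       mean = mean(values))
}
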