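# Detection of collective departures: change-points on group speed give
# candidate decisions; change-points on group heading / heading variance
# anchor the departure direction; three exclusion filters (no clear
# stationary phase, first/last decision of the day, no heading change-point
# in the pre-departure window) mirror the screening applied to field data.

#' Find candidate collective decisions in a group series
#'
#' Candidates are speed change-points at which the group accelerates out of
#' a slow regime.  Each candidate is annotated with the exclusion filters:
#' `no_stationary` (no `stationary_min_s` seconds of mean speed below
#' `stationary_speed_mps` immediately before departure), `first_of_day` /
#' `last_of_day` (possible observer influence), and
#' `no_prewindow_changepoint` (no heading or heading-variance change-point
#' inside the pre-departure window, so no departure direction can be
#' anchored).  Only events with `excluded_reason == "none"` are retained
#' downstream.
#'
#' @param group a [group_series()].
#' @param config a [run_config()].
#' @return list of `decision_event` lists with fields `event_id`, `day_id`,
#'   `t_departure_s`, `window` (start, end, clipped to the day),
#'   `departure_direction_rad`, `destination_direction_rad`,
#'   `t_heading_cp_s`, `stationary_ok`, `excluded_reason`, `truncated`.
#' @export
find_decisions <- function(group, config = run_config()) {
  stopifnot(inherits(group, "group_series"))
  if (nrow(group) == 0L) stop("find_decisions: empty group series")
  events <- list()
  eid <- 0L
  for (d in unique(group$day_id)) {
    day <- group[group$day_id == d, , drop = FALSE]
    sp_ok <- is.finite(day$mean_speed_mps)
    sp <- day$mean_speed_mps[sp_ok]
    tt <- day$time_s[sp_ok]
    if (length(sp) < 10L) next
    cps <- detect_changepoints(sp, target = "mean",
                               penalty = config$cp_penalty_speed,
                               times_s = tt, series_name = "speed")
    if (!length(cps$index)) next

    # segment means around each change-point
    bounds <- c(0L, cps$index - 1L, length(sp))
    seg_mean <- vapply(seq_len(length(bounds) - 1L), function(i) {
      mean(sp[(bounds[i] + 1L):bounds[i + 1L]])
    }, 0)

    hcps <- .heading_changepoints(day, config)

    day_events <- list()
    last_t <- -Inf
    for (i in seq_along(cps$index)) {
      pre_m <- seg_mean[i]; post_m <- seg_mean[i + 1L]
      # a departure leaves the stationary regime: slow before, fast after
      if (!(pre_m < config$stationary_speed_mps &&
              post_m > config$stationary_speed_mps)) next
      # staircase segmentations of one sigmoid ramp give near-duplicate
      # candidates; keep the earliest within a refractory window
      if (cps$times_s[i] - last_t < config$stationary_min_s) next
      last_t <- cps$times_s[i]
      eid <- eid + 1L
      # the penalized segmentation puts its boundary partway up the sigmoid
      # speed ramp; backtrack to the foot of the rise (last sample at or
      # below 10% of the step) for the departure time
      j <- cps$index[i]
      thr <- pre_m + 0.1 * (post_m - pre_m)
      j0 <- j
      while (j > 1L && sp[j - 1L] > thr && j0 - j < 30L &&
               tt[j] - tt[j - 1L] == 1L) {
        j <- j - 1L
      }
      t_dep <- tt[j]
      w <- c(max(t_dep - config$window_pre_s, min(day$time_s)),
             min(t_dep + config$window_post_s, max(day$time_s)))
      truncated <- (t_dep - config$window_pre_s) < min(day$time_s) ||
        (t_dep + config$window_post_s) > max(day$time_s)
      ev <- list(event_id = eid, day_id = d, t_departure_s = t_dep,
                 window = w, truncated = truncated,
                 departure_direction_rad = NA_real_,
                 destination_direction_rad = NA_real_,
                 t_heading_cp_s = NA_integer_,
                 stationary_ok = NA, excluded_reason = "none")
      ev$stationary_ok <- .has_stationary_phase(day, t_dep, config)
      if (!ev$stationary_ok) {
        ev$excluded_reason <- "no_stationary"
      }
      if (ev$excluded_reason == "none") {
        anchor <- .strongest_heading_cp(hcps, t_dep, config)
        if (is.null(anchor)) {
          ev$excluded_reason <- "no_prewindow_changepoint"
        } else {
          ev$t_heading_cp_s <- anchor
          ev$departure_direction_rad <- departure_direction(ev, group, config)
          ev$destination_direction_rad <- destination_direction(ev, group, config)
        }
      }
      day_events[[length(day_events) + 1L]] <- ev
    }
    # first/last-of-day filter applies to the day's candidate set
    if (length(day_events)) {
      keepable <- vapply(day_events, function(e) e$excluded_reason, "")
      if (length(day_events) >= 1L) {
        if (day_events[[1L]]$excluded_reason == "none") {
          day_events[[1L]]$excluded_reason <- "first_of_day"
        }
        n_ev <- length(day_events)
        if (n_ev > 1L && day_events[[n_ev]]$excluded_reason == "none") {
          day_events[[n_ev]]$excluded_reason <- "last_of_day"
        }
      }
    }
    events <- c(events, day_events)
  }
  events
}

# Heading and heading-variance (directedness) change-points of one day.
# Variance change-points are annotated with the sign of the variance step:
# the onset of directed orientation is a variance *drop*.
.heading_changepoints <- function(day, config) {
  out <- list(times = integer(0), strength = numeric(0),
              var_times = integer(0), var_strength = numeric(0),
              var_drop = logical(0))
  h <- unwrap_angle(day$mean_heading_rad)
  ok <- is.finite(h)
  if (sum(ok) >= 10L) {
    cp_h <- detect_changepoints(h[ok], target = "mean",
                                penalty = config$cp_penalty_heading,
                                times_s = day$time_s[ok],
                                series_name = "heading")
    out$times <- cp_h$times_s
    out$strength <- cp_h$strengths / cp_h$penalty
  }
  # directedness = across-individual circular variance of headings
  # (1 - polar order): collapses to ~0 when the group locks onto a common
  # direction, at the vote under voting or at departure under copying
  v <- 1 - day$polar_order
  okv <- is.finite(v)
  if (sum(okv) >= 10L) {
    vv <- v[okv]; tv <- day$time_s[okv]
    cp_v <- detect_changepoints(vv, target = "mean",
                                times_s = tv,
                                series_name = "heading_variance")
    out$var_times <- cp_v$times_s
    out$var_strength <- cp_v$strengths / cp_v$penalty
    # a genuine lock-on: variance drops AND the group is directed afterwards
    out$var_drop <- vapply(cp_v$index, function(i) {
      lo <- max(1L, i - 15L); hi <- min(length(vv), i + 14L)
      post <- mean(vv[i:hi])
      post < mean(vv[lo:(i - 1L)]) && post < config$directedness_max
    }, TRUE)
  }
  out
}

# Anchor for the departure direction inside [t_dep - window_pre, t_dep +
# grace]: the strongest directedness *drop* (the group locking onto a
# common direction: at departure under copying, at the vote under voting);
# heading-mean change-points are the fallback when the variance series has
# none.  Ties go to the earliest time.  NULL if neither series has one.
.strongest_heading_cp <- function(hcps, t_dep, config) {
  lo <- t_dep - config$window_pre_s
  hi <- t_dep + config$heading_cp_grace_s
  pick <- function(times, strength) {
    sel <- times >= lo & times <= hi
    if (!any(sel)) return(NULL)
    t_sel <- times[sel]; s_sel <- strength[sel]
    best <- which(s_sel == max(s_sel))
    t_sel[best][which.min(t_sel[best])]
  }
  anchor <- pick(hcps$var_times[hcps$var_drop], hcps$var_strength[hcps$var_drop])
  if (is.null(anchor)) anchor <- pick(hcps$times, hcps$strength)
  anchor
}

# >= stationary_min_s seconds of data immediately before t_dep, with mean
# group speed below the stationary threshold.
.has_stationary_phase <- function(day, t_dep, config) {
  sel <- day$time_s >= t_dep - config$stationary_min_s & day$time_s < t_dep
  sp <- day$mean_speed_mps[sel]
  sp <- sp[is.finite(sp)]
  if (length(sp) < 0.8 * config$stationary_min_s) return(FALSE)
  mean(sp) < config$stationary_speed_mps
}

#' Departure direction of a decision event
#'
#' Circular mean of the group mean heading over `direction_window_s`
#' seconds (default 10, the approximate length of the moving phase),
#' starting `direction_offset_s` seconds after the strongest heading /
#' heading-variance change-point of the event (skipping the capped-turn
#' alignment transient).  By construction the decision parameter evaluated
#' against this direction reaches 1 during the departure.
#'
#' @param event a `decision_event` with `t_heading_cp_s` set.
#' @param group the [group_series()] the event was found in.
#' @param config a [run_config()].
#' @return direction in `[0, 2*pi)` radians.
#' @export
departure_direction <- function(event, group, config = run_config()) {
  if (is.na(event$t_heading_cp_s)) {
    stop("departure_direction: event has no heading change-point anchor")
  }
  day <- group[group$day_id == event$day_id, , drop = FALSE]
  from <- event$t_heading_cp_s + config$direction_offset_s
  sel <- day$time_s >= from & day$time_s < from + config$direction_window_s
  h <- day$mean_heading_rad[sel]
  h <- h[is.finite(h)]
  if (!length(h)) stop("departure_direction: no heading data in moving phase")
  circular_mean(h)
}

#' Destination direction of a decision event
#'
#' Bearing from the group centroid at departure to the centroid at the end
#' of the post-departure window (the next destination).  Requires a travel
#' phase: at least `min_travel_s` post-departure seconds with group speed
#' above the stationary threshold; otherwise returns `NA` (flagged).
#'
#' @inheritParams departure_direction
#' @param min_travel_s minimum sustained movement (default 60 s).
#' @return bearing in `[0, 2*pi)` radians, or `NA_real_`.
#' @export
destination_direction <- function(event, group, config = run_config(),
                                  min_travel_s = 60L) {
  day <- group[group$day_id == event$day_id, , drop = FALSE]
  post <- day[day$time_s > event$t_departure_s &
                day$time_s <= event$window[2L], , drop = FALSE]
  moving <- sum(is.finite(post$mean_speed_mps) &
                  post$mean_speed_mps > config$stationary_speed_mps)
  if (moving < min_travel_s) return(NA_real_)
  at_dep <- day[day$time_s == event$t_departure_s, , drop = FALSE]
  at_end <- post[which.max(post$time_s), , drop = FALSE]
  if (!nrow(at_dep) || !nrow(at_end)) return(NA_real_)
  dx <- at_end$centroid_x_m - at_dep$centroid_x_m
  dy <- at_end$centroid_y_m - at_dep$centroid_y_m
  if (dx == 0 && dy == 0) return(NA_real_)
  wrap_angle(atan2(dy, dx))
}

#' Retained events
#'
#' @param events output of [find_decisions()].
#' @return the subset with `excluded_reason == "none"`.
#' @export
retained_events <- function(events) {
  Filter(function(e) identical(e$excluded_reason, "none"), events)
}

#' Change-point penalty sensitivity sweep
#'
#' Re-runs [find_decisions()] with the speed/heading penalties scaled by a
#' grid of multipliers, reporting candidate and retained event counts —
#' the robustness check one should run before trusting a detected event
#' set.
#'
#' @param group a [group_series()].
#' @param config a [run_config()].
#' @param multipliers penalty scale factors.
#' @return data.frame `multiplier, n_candidates, n_retained`.
#' @export
penalty_sensitivity <- function(group, config = run_config(),
                                multipliers = c(0.5, 0.75, 1, 1.5, 2)) {
  base_sp <- config$cp_penalty_speed
  base_hd <- config$cp_penalty_heading
  res <- lapply(multipliers, function(m) {
    cfg <- config
    # NULL penalty = automatic; recover its value on a per-day basis by
    # scaling inside detect_changepoints via explicit penalties
    cfg$cp_penalty_speed <- if (is.null(base_sp)) NULL else base_sp * m
    cfg$cp_penalty_heading <- if (is.null(base_hd)) NULL else base_hd * m
    if (is.null(base_sp) || is.null(base_hd)) {
      cfg <- .scale_auto_penalties(group, cfg, m)
    }
    ev <- find_decisions(group, cfg)
    data.frame(multiplier = m, n_candidates = length(ev),
               n_retained = length(retained_events(ev)))
  })
  do.call(rbind, res)
}

# Resolve automatic penalties on the first day's series and scale them, so
# the sweep multiplies a concrete number.
.scale_auto_penalties <- function(group, cfg, m) {
  day <- group[group$day_id == unique(group$day_id)[1L], , drop = FALSE]
  sp <- day$mean_speed_mps[is.finite(day$mean_speed_mps)]
  if (is.null(cfg$cp_penalty_speed) && length(sp) >= 10L) {
    s2 <- max(.noise_sd(sp)^2, 1e-12)
    cfg$cp_penalty_speed <- m * 3 * s2 * log(length(sp))
  }
  h <- unwrap_angle(day$mean_heading_rad)
  h <- h[is.finite(h)]
  if (is.null(cfg$cp_penalty_heading) && length(h) >= 10L) {
    s2 <- max(.noise_sd(h)^2, 1e-12)
    cfg$cp_penalty_heading <- m * 3 * s2 * log(length(h))
  }
  cfg
}
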