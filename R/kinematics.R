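# Per-individual and group-level motion quantities.

#' Instantaneous speed and track heading
#'
#' Forward differences between successive positions on the 1 Hz grid:
#' speed is the Euclidean displacement per second; the track heading is the
#' atan2 of the displacement.  Track heading is `NA` (undefined) when the
#' displacement is zero, and both quantities are `NA` at the last sample of
#' each contiguous block.  Body headings used in the analyses come from the
#' `heading_rad` column (the magnetometer analogue); track headings exist
#' for speed/heading validation only.
#'
#' @param table a [trajectory_table()].
#' @param dt sampling interval in seconds (default 1).
#' @return data.frame `time_s, individual_id, speed_mps, track_heading_rad`.
#' @export
instantaneous_motion <- function(table, dt = 1) {
  stopifnot(inherits(table, "trajectory_table"))
  if (dt <= 0) stop("instantaneous_motion: dt must be > 0")
  pieces <- lapply(split(seq_len(nrow(table)), table$individual_id), function(ix) {
    sub <- table[ix, , drop = FALSE]
    n <- nrow(sub)
    speed <- rep(NA_real_, n)
    trk <- rep(NA_real_, n)
    if (n >= 2L) {
      consec <- diff(sub$time_s) == dt
      dx <- diff(sub$x_m); dy <- diff(sub$y_m)
      disp <- sqrt(dx^2 + dy^2)
      speed[-n][consec] <- disp[consec] / dt
      defined <- consec & disp > 0
      trk[-n][defined] <- wrap_angle(atan2(dy, dx))[defined]
    }
    data.frame(time_s = sub$time_s, individual_id = sub$individual_id,
               speed_mps = speed, track_heading_rad = trk)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Group-level time series
#'
#' Per time step: centroid of member positions, circular mean of member
#' body headings, mean of member instantaneous speeds, polar order (mean
#' resultant length of member heading unit vectors) and member count.
#' Steps at which fewer than `min_coverage` of all individuals have data
#' are dropped; member values are never interpolated.
#'
#' @param table a [trajectory_table()].
#' @param config a [run_config()] (uses `min_coverage`).
#' @param speed one of `"mean_member"` (default; mean of individual speeds)
#'   or `"centroid"` (speed of the centroid track).
#' @return a `group_series` data.frame with columns `time_s, centroid_x_m,
#'   centroid_y_m, mean_heading_rad, mean_speed_mps, polar_order, n_members`
#'   plus attribute `day_id` per row.
#' @export
group_series <- function(table, config = run_config(),
                         speed = c("mean_member", "centroid")) {
  stopifnot(inherits(table, "trajectory_table"))
  speed <- match.arg(speed)
  ids <- unique(table$individual_id)
  if (length(ids) < 2L) stop("group_series: need at least 2 individuals")
  motion <- instantaneous_motion(table)
  tab <- table
  tab$speed_mps <- motion$speed_mps[match(
    paste(tab$individual_id, tab$time_s),
    paste(motion$individual_id, motion$time_s))]

  groups <- split(seq_len(nrow(tab)), paste(tab$day_id, tab$time_s, sep = "\r"))
  stat <- vapply(groups, function(ix) {
    h <- tab$heading_rad[ix]
    c(mean(tab$x_m[ix]), mean(tab$y_m[ix]), circular_mean(h),
      mean(tab$speed_mps[ix]),  # NA at block ends propagates
      resultant_length(h), length(ix))
  }, numeric(6))
  first <- vapply(groups, `[`, 0L, 1L)
  out <- data.frame(
    day_id = tab$day_id[first], time_s = tab$time_s[first],
    centroid_x_m = stat[1L, ], centroid_y_m = stat[2L, ],
    mean_heading_rad = stat[3L, ], mean_speed_mps = stat[4L, ],
    polar_order = stat[5L, ], n_members = as.integer(stat[6L, ])
  )
  out <- out[order(out$day_id, out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out <- out[out$n_members >= max(2L, ceiling(config$min_coverage * length(ids))), ,
             drop = FALSE]
  if (speed == "centroid") {
    sp <- rep(NA_real_, nrow(out))
    for (d in unique(out$day_id)) {
      ix <- which(out$day_id == d)
      if (length(ix) >= 2L) {
        consec <- diff(out$time_s[ix]) == 1L
        disp <- sqrt(diff(out$centroid_x_m[ix])^2 + diff(out$centroid_y_m[ix])^2)
        sp[ix[-length(ix)]][consec] <- disp[consec]
      }
    }
    out$mean_speed_mps <- sp
  }
  class(out) <- c("group_series", "data.frame")
  out
}
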