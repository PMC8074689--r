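# Data model and I/O: the trajectory table is the universal input of the
# pipeline; no downstream stage reads files directly.

TRAJ_COLS <- c("time_s", "individual_id", "x_m", "y_m", "heading_rad")

#' Construct and validate a trajectory table
#'
#' The standard container for per-individual 1 Hz tracking data: integer
#' time in seconds, an individual label, planar position in metres (local
#' tangent-plane projection) and body heading in radians (mathematical
#' convention, wrapped to `[0, 2*pi)`).  An optional `day_id` groups
#' decisions for first/last-of-day filtering; it defaults to a single day.
#'
#' @param df data.frame with columns `time_s`, `individual_id`, `x_m`,
#'   `y_m`, `heading_rad` and optionally `day_id`.
#' @return a validated `trajectory_table` (a data.frame subclass), sorted by
#'   `(individual_id, time_s)`.
#' @export
trajectory_table <- function(df) {
  miss <- setdiff(TRAJ_COLS, names(df))
  if (length(miss)) {
    stop("trajectory_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"day_id" %in% names(df)) df$day_id <- rep("day1", nrow(df))
  df <- df[, c(TRAJ_COLS, "day_id")]
  df$time_s <- as.integer(df$time_s)
  df$individual_id <- as.character(df$individual_id)
  df$day_id <- as.character(df$day_id)
  for (col in c("x_m", "y_m", "heading_rad")) {
    if (!is.numeric(df[[col]])) stop("trajectory_table: ", col, " not numeric")
    if (any(!is.finite(df[[col]]))) {
      stop("trajectory_table: non-finite values in ", col)
    }
  }
  if (any(df$heading_rad < 0 | df$heading_rad >= 2 * pi)) {
    stop("trajectory_table: heading_rad outside [0, 2*pi); wrap or convert first")
  }
  key <- paste(df$individual_id, df$time_s, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("trajectory_table: duplicate (individual_id, time_s): (%s, %d)",
                 dup$individual_id, dup$time_s))
  }
  df <- df[order(df$individual_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trajectory_table", "data.frame")
  df
}

#' Read a trajectory CSV
#'
#' Columns `time_s,individual_id,x_m,y_m,heading_rad[,day_id]`.  Headings may
#' be stored in radians (default) or compass-free degrees; degrees are
#' converted at this boundary so that everything downstream sees one
#' convention.
#'
#' @param path CSV file path.
#' @param heading_unit `"rad"` or `"deg"`.
#' @param schema optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(time_s = "t")`.
#' @return a validated [trajectory_table()].
#' @export
read_trajectories <- function(path, heading_unit = c("rad", "deg"),
                              schema = NULL) {
  heading_unit <- match.arg(heading_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df)) {
        stop("read_trajectories: schema column not in file: ", schema[[std]])
      }
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  miss <- setdiff(TRAJ_COLS, names(df))
  if (length(miss)) {
    stop("read_trajectories: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (heading_unit == "deg") {
    df$heading_rad <- wrap_angle(df$heading_rad * pi / 180)
  }
  trajectory_table(df)
}

#' Write a trajectory CSV
#'
#' Positions are written with 6 decimal places and headings with 9, so that
#' [read_trajectories()] inverts the write bit-exactly at that precision.
#'
#' @param table a [trajectory_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(table, path) {
  stopifnot(inherits(table, "trajectory_table"))
  out <- as.data.frame(table)
  out$x_m <- sprintf("%.6f", out$x_m)
  out$y_m <- sprintf("%.6f", out$y_m)
  out$heading_rad <- sprintf("%.9f", out$heading_rad)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular projection about the dataset centroid; exact enough at
#' the ~100 m scales of group movement.  Provided for users with geographic
#' coordinates; the rest of the package works in planar metres.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @return data.frame with `x_m`, `y_m` (east, north of the centroid).
#' @export
lonlat_to_xy <- function(lon, lat) {
  R_earth <- 6371008.8
  lat0 <- mean(lat) * pi / 180
  lon0 <- mean(lon) * pi / 180
  data.frame(
    x_m = (lon * pi / 180 - lon0) * cos(lat0) * R_earth,
    y_m = (lat * pi / 180 - lat0) * R_earth
  )
}

#' Analysis configuration
#'
#' All tunable parameters of the detection/metrics/leadership stages with
#' their defaults.  Window lengths are in seconds on the 1 Hz grid.
#'
#' @param window_pre_s,window_post_s event window half-widths around the
#'   departure time (default 100 s each side).
#' @param max_lag_s cross-correlation maximum lag (default 100 s; clamped to
#'   what a truncated event window supports, see [cross_correlate()]).
#' @param bootstrap_n bootstrap resamples for median CIs (default 1000).
#' @param rng_seed seed echoed in outputs.
#' @param leader_threshold minimum windowed heading correlation for a dyad
#'   step to be scored (default 0.9).
#' @param leader_window_s,leader_max_shift_s dyad correlation window and
#'   maximum shift (defaults 15 s, 10 s at 1 Hz).
#' @param cp_penalty_speed,cp_penalty_heading change-point penalties as
#'   multiples of the BIC-like unit `sigma^2 * log(n)`; `NULL` = automatic.
#' @param stationary_speed_mps,stationary_min_s pre-departure stationary
#'   phase definition: mean speed below this for at least this long
#'   (defaults 0.2 m/s, 60 s).
#' @param direction_window_s seconds of group mean heading averaged to give
#'   the departure direction (default 10, the approximate length of the
#'   moving phase).
#' @param direction_offset_s seconds skipped between the anchoring
#'   change-point and the direction window (default 5): at a capped turn
#'   rate of 0.75 rad/s the alignment transient lasts up to ~4 s, and
#'   averaging over it biases the direction estimate.
#' @param heading_cp_grace_s how far past the departure time a heading
#'   change-point may fall and still anchor the departure direction
#'   (default 15 s; copying groups only align as they depart).
#' @param variance_window_s sliding window for the temporal heading
#'   variance utility series (default 15 s).
#' @param directedness_max across-individual circular variance below which
#'   the group counts as directed (default 0.25, i.e. polar order above
#'   0.75); a heading-variance change-point anchors a departure direction
#'   only if the group is directed after it.
#' @param min_coverage fraction of individuals that must have data for a
#'   time step to be retained in group series (default 0.8).
#' @param min_decided_steps dyads with fewer decided steps are dropped from
#'   transitivity binarization (default 10).
#' @return a `run_config` list.
#' @export
run_config <- function(window_pre_s = 100L, window_post_s = 100L,
                       max_lag_s = NULL, bootstrap_n = 1000L,
                       rng_seed = 1L, leader_threshold = 0.9,
                       leader_window_s = 15L, leader_max_shift_s = 10L,
                       cp_penalty_speed = NULL, cp_penalty_heading = NULL,
                       stationary_speed_mps = 0.2, stationary_min_s = 60L,
                       direction_window_s = 10L, direction_offset_s = 5L,
                       heading_cp_grace_s = 15L,
                       variance_window_s = 15L, directedness_max = 0.25,
                       min_coverage = 0.8, min_decided_steps = 10L) {
  cfg <- list(
    window_pre_s = as.integer(window_pre_s),
    window_post_s = as.integer(window_post_s),
    max_lag_s = if (is.null(max_lag_s)) NULL else as.integer(max_lag_s),
    bootstrap_n = as.integer(bootstrap_n),
    rng_seed = as.integer(rng_seed),
    leader_threshold = leader_threshold,
    leader_window_s = as.integer(leader_window_s),
    leader_max_shift_s = as.integer(leader_max_shift_s),
    cp_penalty_speed = cp_penalty_speed,
    cp_penalty_heading = cp_penalty_heading,
    stationary_speed_mps = stationary_speed_mps,
    stationary_min_s = as.integer(stationary_min_s),
    direction_window_s = as.integer(direction_window_s),
    direction_offset_s = as.integer(direction_offset_s),
    heading_cp_grace_s = as.integer(heading_cp_grace_s),
    variance_window_s = as.integer(variance_window_s),
    directedness_max = directedness_max,
    min_coverage = min_coverage,
    min_decided_steps = as.integer(min_decided_steps)
  )
  if (cfg$window_pre_s <= 0L || cfg$window_post_s <= 0L) {
    stop("run_config: window lengths must be positive")
  }
  if (cfg$bootstrap_n < 1L) stop("run_config: bootstrap_n must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}
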