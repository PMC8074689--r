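# Agent-based model of collective departures.  A cohesive, stationary
# group; each agent starts to move (at sigma units/s) after its own
# movement-initiation time drawn from a normal distribution, and while
# moving turns (at most max_turn_rad per step) toward the circular mean of
# its neighbours' orientations.  Under the voting mechanisms agents first
# orient, while still stationary, toward a personal vote direction drawn
# from a von Mises distribution after a vote-initiation time.  "Copying"
# has no vote; "all_vote" makes everyone vote; "sub_vote" a fraction.

#' Simulator configuration
#'
#' Defaults give a 10-agent group with a 60 s stationary phase, votes (when
#' the mechanism has them) starting around 30 s, and movement onset around
#' 60 s, producing the sigmoid group-speed rise of a collective departure
#' over a 220 s run.
#'
#' @param mechanism `"copying"`, `"all_vote"` or `"sub_vote"`.
#' @param n_agents number of agents (default 10).
#' @param speed_sigma movement speed sigma in units/s (default 1); agent
#'   speed is exactly 0 or `speed_sigma`.
#' @param max_turn_rad maximum turn per 1 s step (default 0.75 rad).
#' @param vote_fraction fraction of agents voting under `sub_vote`
#'   (default 0.3; ignored otherwise).
#' @param kappa von Mises concentration of vote directions (default 4).
#' @param move_init_mean_s,move_init_sd_s normal distribution of per-agent
#'   movement-initiation times (defaults 60 s, 5 s).
#' @param vote_init_mean_s,vote_init_sd_s normal distribution of per-agent
#'   vote-initiation times (defaults 30 s, 5 s); must precede movement
#'   initiation in expectation.
#' @param topology_k number of nearest neighbours averaged when turning
#'   (`NULL`, the default, means all other group members).
#' @param init_pos_sd positional scatter sd of the initial group (default 2).
#' @param heading_wander_sd sd (radians/step) of the wrapped-Gaussian
#'   heading jitter of stationary, non-voting agents (default 0.05):
#'   grazing animals fidget, and exactly constant headings would make
#'   pre-departure windows degenerate (zero variance) for correlation
#'   statistics.  Jitter steps are clamped at `max_turn_rad` like every
#'   other turn.
#' @param target_direction_rad centre of the von Mises vote distribution;
#'   `NULL` (default) draws it uniformly per run.
#' @param n_steps run length in 1 s steps (default 220).
#' @param seed RNG seed for [run_simulation()].
#' @return an `agent_config` list.
#' @export
agent_config <- function(mechanism = c("copying", "all_vote", "sub_vote"),
                         n_agents = 10L, speed_sigma = 1,
                         max_turn_rad = 0.75, vote_fraction = 0.3,
                         kappa = 4, move_init_mean_s = 60,
                         move_init_sd_s = 5, vote_init_mean_s = 30,
                         vote_init_sd_s = 5, topology_k = NULL,
                         init_pos_sd = 2, heading_wander_sd = 0.05,
                         target_direction_rad = NULL,
                         n_steps = 220L, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (vote_fraction <= 0 || vote_fraction > 1) {
    stop("agent_config: vote_fraction must be in (0, 1]")
  }
  if (max_turn_rad <= 0) stop("agent_config: max_turn_rad must be > 0")
  if (kappa < 0) stop("agent_config: kappa must be >= 0")
  if (n_agents < 2L) stop("agent_config: need >= 2 agents")
  if (mechanism != "copying" && vote_init_mean_s >= move_init_mean_s) {
    stop("agent_config: vote initiation must precede movement initiation in expectation")
  }
  structure(list(mechanism = mechanism, n_agents = as.integer(n_agents),
                 speed_sigma = speed_sigma, max_turn_rad = max_turn_rad,
                 vote_fraction = vote_fraction, kappa = kappa,
                 move_init_mean_s = move_init_mean_s,
                 move_init_sd_s = move_init_sd_s,
                 vote_init_mean_s = vote_init_mean_s,
                 vote_init_sd_s = vote_init_sd_s,
                 topology_k = if (is.null(topology_k)) NULL else as.integer(topology_k),
                 init_pos_sd = init_pos_sd,
                 heading_wander_sd = heading_wander_sd,
                 target_direction_rad = target_direction_rad,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "agent_config")
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` degenerates to the uniform
#' circular distribution.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1L])
      f <- (1 + r0 * z) / (r0 + z)
      cc <- kappa * (r0 - f)
      if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
        out[i] <- wrap_angle(mu + sign(u[3L] - 0.5) * acos(f))
        break
      }
    }
  }
  out
}

#' Initial agent states
#'
#' Positions normally scattered about the origin, all speeds exactly 0,
#' headings uniform; per-agent initiation times (and, for voting
#' mechanisms, voter identities and vote directions) are drawn once here.
#' Consumes the current RNG stream; see [run_simulation()] for seeding.
#'
#' @param config an [agent_config()].
#' @return an `agent_states` list of vectors: `x`, `y`, `heading`, `speed`,
#'   `move_init_s`, `is_voter`, `vote_init_s`, `vote_angle`,
#'   `target_direction_rad`.
#' @export
init_agents <- function(config) {
  n <- config$n_agents
  target <- if (is.null(config$target_direction_rad)) {
    stats::runif(1, 0, 2 * pi)
  } else config$target_direction_rad
  st <- list(
    x = stats::rnorm(n, 0, config$init_pos_sd),
    y = stats::rnorm(n, 0, config$init_pos_sd),
    heading = stats::runif(n, 0, 2 * pi),
    speed = rep(0, n)
  )
  class(st) <- "agent_states"
  .plan_event(st, config, target)
}

# (Re)draw one departure plan onto existing states: vote target, per-agent
# directional preferences / votes, vote- and movement-initiation times.
# Called by init_agents and again per event by simulate_dataset.
.plan_event <- function(st, config, target = NULL) {
  n <- config$n_agents
  if (is.null(target)) {
    target <- if (is.null(config$target_direction_rad)) {
      stats::runif(1, 0, 2 * pi)
    } else config$target_direction_rad
  }
  st$target_direction_rad <- target
  st$move_init_s <- stats::rnorm(n, config$move_init_mean_s, config$move_init_sd_s)
  st$is_voter <- rep(FALSE, n)
  st$vote_init_s <- rep(Inf, n)
  st$vote_angle <- rep(NA_real_, n)
  if (config$mechanism == "copying") {
    # copiers carry a directional preference too, but express it only in
    # motion: initiators head toward it, everyone aligns to moving
    # neighbours
    st$vote_angle <- rvonmises(n, target, config$kappa)
  } else {
    voters <- if (config$mechanism == "all_vote") seq_len(n) else {
      sample(n, max(1L, round(config$vote_fraction * n)))
    }
    st$is_voter[voters] <- TRUE
    st$vote_init_s[voters] <- stats::rnorm(length(voters),
                                           config$vote_init_mean_s,
                                           config$vote_init_sd_s)
    st$vote_angle[voters] <- rvonmises(length(voters), target, config$kappa)
  }
  st
}

#' Advance the agent set by one time step
#'
#' Synchronous update: all turn targets are taken from the previous step's
#' headings.  Agents past their movement-initiation time move at
#' `speed_sigma` and turn toward the circular mean heading of their moving
#' neighbours (all of them by default, the `topology_k` nearest when set);
#' an initiator with no moving neighbour heads for its own preferred
#' direction — under copying this is how directional information enters,
#' with the first mover, and spreads through alignment; stationary
#' voters past their vote-initiation time turn toward their vote angle;
#' the remaining (idle, stationary) agents make a small wander turn of sd
#' `heading_wander_sd`.  All turns are clamped at `max_turn_rad`.
#'
#' @param states an `agent_states` list.
#' @param config an [agent_config()].
#' @param t current time step (1-based, seconds).
#' @return updated `agent_states`.
#' @export
step_agents <- function(states, config, t) {
  n <- config$n_agents
  h_prev <- states$heading
  moving <- t >= states$move_init_s
  voting <- !moving & states$is_voter & t >= states$vote_init_s
  new_h <- h_prev
  if (any(moving)) {
    k <- config$topology_k
    for (i in which(moving)) {
      others <- which(moving)[which(moving) != i]
      if (!is.null(k) && k < length(others)) {
        d2 <- (states$x[others] - states$x[i])^2 +
          (states$y[others] - states$y[i])^2
        others <- others[order(d2)][seq_len(k)]
      }
      # align to moving neighbours; an agent with a directional preference
      # (its drawn von Mises angle) keeps weighing it like one extra
      # neighbour, so the travel consensus settles on the preference
      # mixture rather than on the pre-departure milling headings
      angles <- h_prev[others]
      if (is.finite(states$vote_angle[i])) {
        angles <- c(angles, states$vote_angle[i])
      }
      if (length(angles)) {
        tgt <- circular_mean(angles)
        if (!is.na(tgt)) {
          new_h[i] <- turn_toward(h_prev[i], tgt, config$max_turn_rad)
        }
      }
    }
  }
  if (any(voting)) {
    new_h[voting] <- turn_toward(h_prev[voting], states$vote_angle[voting],
                                 config$max_turn_rad)
  }
  idle <- !moving & !voting
  if (any(idle) && config$heading_wander_sd > 0) {
    wander <- stats::rnorm(sum(idle), 0, config$heading_wander_sd)
    wander <- pmin(abs(wander), config$max_turn_rad) * sign(wander)
    new_h[idle] <- wrap_angle(h_prev[idle] + wander)
  }
  states$heading <- new_h
  states$speed <- ifelse(moving, config$speed_sigma, 0)
  states$x <- states$x + states$speed * cos(new_h)
  states$y <- states$y + states$speed * sin(new_h)
  states
}

#' Run one simulated collective departure
#'
#' @param config an [agent_config()].
#' @param day_id day label stamped on the output (default `"sim"`).
#' @return list with `table` (a [trajectory_table()] at 1 Hz) and `truth`,
#'   the generator's ground truth: `t_departure_s` (median realized
#'   movement-initiation time, rounded), `move_init_s`, `vote_init_s`,
#'   `target_direction_rad`, `departure_direction_rad` (circular mean of
#'   the realized group mean heading over the 10 s after departure) and
#'   `mechanism`.
#' @export
run_simulation <- function(config, day_id = "sim") {
  with_rng(config$seed, {
    st <- init_agents(config)
    n <- config$n_agents
    n_steps <- config$n_steps
    recs <- vector("list", n_steps)
    mean_heads <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      st <- step_agents(st, config, t)
      stopifnot(all(st$speed %in% c(0, config$speed_sigma)))
      recs[[t]] <- data.frame(
        time_s = t, individual_id = sprintf("a%02d", seq_len(n)),
        x_m = st$x, y_m = st$y, heading_rad = wrap_angle(st$heading),
        day_id = day_id
      )
      mean_heads[t] <- circular_mean(st$heading)
    }
    tab <- trajectory_table(do.call(rbind, recs))
    # departure onset = the moment movement becomes collective (the first
    # follower joins the initiator); a lone early mover is not yet a group
    # departure and the group speed ramp is not yet detectable
    t_dep <- as.integer(ceiling(sort(st$move_init_s)[2L]))
    # realized departure direction: the settled travel heading, measured
    # after the initiation spread plus turn-clamped convergence (~<= 20 s)
    dep_sel <- seq.int(min(t_dep + 20L, n_steps),
                       min(t_dep + 50L, n_steps))
    truth <- list(
      t_departure_s = t_dep,
      move_init_s = st$move_init_s,
      vote_init_s = st$vote_init_s,
      target_direction_rad = st$target_direction_rad,
      departure_direction_rad = circular_mean(mean_heads[dep_sel], na.rm = TRUE),
      t_move_median_s = as.integer(round(stats::median(st$move_init_s))),
      mechanism = config$mechanism
    )
    list(table = tab, truth = truth)
  })
}

#' Add GPS / magnetometer style sensor noise
#'
#' Independent Gaussian jitter on positions and wrapped-Gaussian jitter on
#' headings.
#'
#' @param table a [trajectory_table()].
#' @param gps_sd_m position noise sd, metres (>= 0).
#' @param heading_sd_rad heading noise sd, radians (>= 0).
#' @param seed RNG seed.
#' @return a noisy [trajectory_table()].
#' @export
add_sensor_noise <- function(table, gps_sd_m = 0.3, heading_sd_rad = 0.1,
                             seed = NULL) {
  stopifnot(inherits(table, "trajectory_table"))
  if (gps_sd_m < 0 || heading_sd_rad < 0) {
    stop("add_sensor_noise: sds must be >= 0")
  }
  with_rng(seed, {
    n <- nrow(table)
    df <- as.data.frame(table)
    if (gps_sd_m > 0) {
      df$x_m <- df$x_m + stats::rnorm(n, 0, gps_sd_m)
      df$y_m <- df$y_m + stats::rnorm(n, 0, gps_sd_m)
    }
    if (heading_sd_rad > 0) {
      df$heading_rad <- wrap_angle(df$heading_rad +
                                     stats::rnorm(n, 0, heading_sd_rad))
    }
    trajectory_table(df)
  })
}

#' Cohesion and consensus summary of a completed run
#'
#' `split` is whether the distance-threshold graph on final positions is
#' disconnected; `consensus` is the final polar order.
#'
#' @param table a [trajectory_table()].
#' @param split_distance edge threshold in metres/units (default 20).
#' @return list `split` (logical), `consensus` (`[0, 1]`).
#' @export
cohesion_metrics <- function(table, split_distance = 20) {
  stopifnot(inherits(table, "trajectory_table"))
  last_t <- max(table$time_s)
  fin <- table[table$time_s == last_t, , drop = FALSE]
  n <- nrow(fin)
  d <- as.matrix(stats::dist(cbind(fin$x_m, fin$y_m)))
  adj <- d <= split_distance
  # connectivity by BFS
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  list(split = !all(seen),
       consensus = resultant_length(fin$heading_rad))
}

#' Prediction statistics for a decision mechanism
#'
#' Simulates a pool of independent collective departures, computes the
#' per-event CorrMax and Sym statistics (decision parameter against the
#' realized departure direction, cross-correlated with group mean speed),
#' then resamples `n_decisions`-event subsets with replacement and reports
#' the mean and 95% percentile interval of the subset medians — the
#' model's predicted sampling distribution for a dataset of that size.
#'
#' @param config an [agent_config()]; its `seed` field is ignored here.
#' @param n_events size of the simulated event pool (default 50).
#' @param n_decisions events per resampled dataset (default 21).
#' @param n_resample number of resampled datasets (default 1000).
#' @param seed RNG seed controlling the whole procedure.
#' @param run_cfg a [run_config()] for the metrics stage.
#' @return list with `per_event` (data.frame `corr_max_lag_s,
#'   symmetry_index`), `corr_max` and `symmetry` summaries (`mean`, `ci`,
#'   `median`), `n_events`, `n_decisions`, `n_resample`, `mechanism`.
#' @export
simulate_predictions <- function(config, n_events = 50L, n_decisions = 21L,
                                 n_resample = 1000L, seed = 1L,
                                 run_cfg = run_config()) {
  if (n_events < n_decisions) {
    stop("simulate_predictions: event pool smaller than n_decisions")
  }
  with_rng(seed, {
    seeds <- sample.int(2^31 - 2, n_events)
    per <- vapply(seq_len(n_events), function(i) {
      cfg <- config
      cfg$seed <- seeds[i]
      sim <- run_simulation(cfg)
      st <- .event_stats_from_truth(sim, run_cfg)
      c(st$corr_max_lag_s, st$symmetry_index)
    }, numeric(2))
    cm <- per[1L, ]; sy <- per[2L, ]
    med_cm <- numeric(n_resample); med_sy <- numeric(n_resample)
    for (b in seq_len(n_resample)) {
      ix <- sample.int(n_events, n_decisions, replace = TRUE)
      med_cm[b] <- stats::median(cm[ix])
      med_sy[b] <- stats::median(sy[ix])
    }
    list(per_event = data.frame(corr_max_lag_s = cm, symmetry_index = sy),
         corr_max = list(mean = mean(med_cm),
                         median = stats::median(med_cm),
                         ci = unname(stats::quantile(med_cm, c(0.025, 0.975)))),
         symmetry = list(mean = mean(med_sy),
                         median = stats::median(med_sy),
                         ci = unname(stats::quantile(med_sy, c(0.025, 0.975)))),
         n_events = n_events, n_decisions = n_decisions,
         n_resample = n_resample, mechanism = config$mechanism)
  })
}

# CorrMax / Sym of one simulated run, anchored at the generator's true
# departure time with the realized (measured) departure direction — the
# detection stage is exercised separately.
.event_stats_from_truth <- function(sim, run_cfg) {
  gs <- group_series(sim$table, run_cfg)
  ev <- list(event_id = 1L, day_id = sim$table$day_id[1L],
             t_departure_s = sim$truth$t_departure_s,
             window = c(max(sim$truth$t_departure_s - run_cfg$window_pre_s,
                            min(gs$time_s)),
                        min(sim$truth$t_departure_s + run_cfg$window_post_s,
                            max(gs$time_s))),
             departure_direction_rad = sim$truth$departure_direction_rad,
             destination_direction_rad = NA_real_,
             t_heading_cp_s = sim$truth$t_departure_s,
             stationary_ok = TRUE, excluded_reason = "none",
             truncated = FALSE)
  curve <- decision_curve(ev, gs, "departure", run_cfg)
  cross_correlate(curve, run_cfg$max_lag_s, clamp = TRUE)
}

#' Simulate a day of repeated collective departures
#'
#' One continuous simulation of a day containing `n_events` collective
#' departures: after each travel phase the group halts and rests for
#' `rest_s` seconds — a short dispersal burst (`dispersal_s` seconds of
#' strong heading wander, the animals turning away to graze) followed by
#' quiet jitter — then a fresh departure plan (vote target, preferences,
#' initiation times) is drawn and the next event unfolds.  Positions and
#' headings are continuous throughout; the dispersal re-randomises
#' orientations so the polar order between departures returns to a low
#' grazing baseline.  Because the first and last decisions of a day are filtered
#' as possibly observer-influenced, ask for two more events than you want
#' retained.
#'
#' @param config an [agent_config()]; its `seed` field is ignored here.
#' @param n_events number of departures in the day (default 23).
#' @param rest_s resting seconds between events (default 120).
#' @param dispersal_s,dispersal_sd length and per-step heading-wander sd of
#'   the dispersal burst opening each rest (defaults 30 s, 0.5 rad).
#' @param day_id day label (default `"day1"`).
#' @param seed RNG seed for the whole day.
#' @return list with `table` (one continuous [trajectory_table()]) and
#'   `truths`, the per-event ground truth on the day clock.
#' @export
simulate_dataset <- function(config, n_events = 23L, rest_s = 120L,
                             dispersal_s = 30L, dispersal_sd = 0.5,
                             day_id = "day1", seed = 1L) {
  with_rng(seed, {
    n <- config$n_agents
    ids <- sprintf("a%02d", seq_len(n))
    st <- init_agents(config)
    truths <- vector("list", n_events)
    blocks <- vector("list", 2L * n_events)
    idle <- list(move_init_s = rep(Inf, n), is_voter = rep(FALSE, n),
                 vote_init_s = rep(Inf, n), vote_angle = rep(NA_real_, n))
    t_off <- 0L
    for (e in seq_len(n_events)) {
      if (e > 1L) st <- .plan_event(st, config)
      n_steps <- config$n_steps
      xs <- matrix(0, n_steps, n); ys <- matrix(0, n_steps, n)
      hs <- matrix(0, n_steps, n)
      mean_heads <- numeric(n_steps)
      for (t in seq_len(n_steps)) {
        st <- step_agents(st, config, t)
        xs[t, ] <- st$x; ys[t, ] <- st$y; hs[t, ] <- wrap_angle(st$heading)
        mean_heads[t] <- circular_mean(st$heading)
      }
      t_dep_local <- as.integer(ceiling(sort(st$move_init_s)[2L]))
      dep_sel <- seq.int(min(t_dep_local + 20L, n_steps),
                         min(t_dep_local + 50L, n_steps))
      truths[[e]] <- list(
        t_departure_s = t_off + t_dep_local,
        move_init_s = st$move_init_s + t_off,
        vote_init_s = st$vote_init_s + t_off,
        target_direction_rad = st$target_direction_rad,
        departure_direction_rad = circular_mean(mean_heads[dep_sel],
                                                na.rm = TRUE),
        mechanism = config$mechanism, event_index = e
      )
      blocks[[2L * e - 1L]] <- data.frame(
        time_s = rep(t_off + seq_len(n_steps), each = n),
        individual_id = rep(ids, n_steps),
        x_m = as.vector(t(xs)), y_m = as.vector(t(ys)),
        heading_rad = as.vector(t(hs)), day_id = day_id
      )
      t_off <- t_off + n_steps
      if (e < n_events && rest_s > 0L) {
        st_rest <- utils::modifyList(st, idle)
        cfg_disp <- config
        cfg_disp$heading_wander_sd <- dispersal_sd
        hh <- matrix(0, rest_s, n)
        for (t in seq_len(rest_s)) {
          st_rest <- step_agents(st_rest,
                                 if (t <= dispersal_s) cfg_disp else config, t)
          hh[t, ] <- wrap_angle(st_rest$heading)
        }
        blocks[[2L * e]] <- data.frame(
          time_s = rep(t_off + seq_len(rest_s), each = n),
          individual_id = rep(ids, rest_s),
          x_m = rep(st_rest$x, rest_s), y_m = rep(st_rest$y, rest_s),
          heading_rad = as.vector(t(hh)), day_id = day_id
        )
        st$heading <- st_rest$heading
        t_off <- t_off + rest_s
      }
    }
    list(table = trajectory_table(do.call(rbind, blocks)), truths = truths)
  })
}
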