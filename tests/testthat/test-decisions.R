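# One simulated 5-event day shared across detection tests (seeded).
day_fixture <- local({
  cache <- new.env()
  function(mechanism = "copying", seed = 42L, n_events = 5L) {
    key <- paste(mechanism, seed, n_events)
    if (is.null(cache[[key]])) {
      ds <- simulate_dataset(agent_config(mechanism = mechanism),
                             n_events = n_events, seed = seed)
      gs <- group_series(ds$table)
      cache[[key]] <- list(ds = ds, gs = gs,
                           events = find_decisions(gs, run_config()))
    }
    cache[[key]]
  }
})

test_that("a multi-departure day yields one candidate per true event, filters applied", {
  fx <- day_fixture()
  ev <- fx$events
  expect_length(ev, 5L)
  reasons <- vapply(ev, `[[`, "", "excluded_reason")
  expect_equal(reasons[1], "first_of_day")
  expect_equal(reasons[5], "last_of_day")
  expect_equal(sum(reasons == "none"), 3L)
  tru <- vapply(fx$ds$truths, `[[`, 0L, "t_departure_s")
  det <- vapply(ev, `[[`, 0L, "t_departure_s")
  expect_true(all(abs(det - tru) <= 10))
})

test_that("detected departure times match ground truth within +-3 s in >= 90% of events", {
  hits <- 0L; total <- 0L
  for (seed in c(42L, 43L, 44L)) {
    fx <- day_fixture(seed = seed)
    tru <- vapply(fx$ds$truths, `[[`, 0L, "t_departure_s")
    for (e in retained_events(fx$events)) {
      total <- total + 1L
      hits <- hits + (min(abs(tru - e$t_departure_s)) <= 3L)
    }
  }
  expect_gte(total, 8L)
  expect_gte(hits / total, 0.9)
})

test_that("departure direction recovers an engineered vote angle within 0.1 rad", {
  # all agents vote tightly around a known angle: the departure direction is
  # the known target
  ds <- simulate_dataset(agent_config("all_vote", kappa = 60,
                                      target_direction_rad = 1.0),
                         n_events = 4L, seed = 7L)
  gs <- group_series(ds$table)
  kept <- retained_events(find_decisions(gs, run_config()))
  expect_gte(length(kept), 2L)
  for (e in kept) {
    expect_lt(abs(angle_diff(e$departure_direction_rad, 1.0)), 0.1)
  }
})

test_that("decision parameter reaches ~1 within the moving phase of retained events", {
  fx <- day_fixture()
  cfg <- run_config()
  for (e in retained_events(fx$events)) {
    cu <- decision_curve(e, fx$gs, "departure", cfg)
    mov <- cu$r[cu$rel_time_s >= 0 & cu$rel_time_s <= 30]
    expect_gte(max(mov, na.rm = TRUE), 0.99)
  }
})

test_that("continuous drift without a stationary phase is not a retained decision", {
  # group always moving: speeds never below the stationary threshold
  df <- expand.grid(time_s = 1:400, individual_id = sprintf("d%d", 1:4),
                    stringsAsFactors = FALSE)
  df$x_m <- df$time_s * 0.6 + (df$time_s > 200) * (df$time_s - 200) * 0.5
  df$y_m <- match(df$individual_id, unique(df$individual_id))
  df$heading_rad <- 0
  gs <- group_series(trajectory_table(df))
  ev <- find_decisions(gs, run_config())
  expect_true(all(vapply(ev, `[[`, "", "excluded_reason") != "none"))
})

test_that("destination direction: straight-line travel matches departure direction", {
  fx <- day_fixture()
  kept <- retained_events(fx$events)
  dep <- vapply(kept, `[[`, 0, "departure_direction_rad")
  dst <- vapply(kept, `[[`, 0, "destination_direction_rad")
  ok <- is.finite(dep) & is.finite(dst)
  expect_gte(sum(ok), 2L)
  expect_true(all(abs(angle_diff(dep[ok], dst[ok])) < 0.2))
})

test_that("departure vs destination directions strongly correlated across events", {
  dep <- c(); dst <- c()
  for (seed in c(42L, 43L, 44L)) {
    for (e in retained_events(day_fixture(seed = seed)$events)) {
      dep <- c(dep, e$departure_direction_rad)
      dst <- c(dst, e$destination_direction_rad)
    }
  }
  ok <- is.finite(dep) & is.finite(dst)
  expect_gt(circular_correlation(dep[ok], dst[ok]), 0.8)
})

test_that("penalty sensitivity sweep is monotone-ish and returns the grid", {
  fx <- day_fixture()
  sens <- penalty_sensitivity(fx$gs, run_config(), multipliers = c(0.5, 1, 2))
  expect_equal(sens$multiplier, c(0.5, 1, 2))
  expect_true(all(sens$n_candidates >= sens$n_retained))
  expect_gte(min(sens$n_retained), 1L)
})

test_that("find_decisions input contracts", {
  fx <- day_fixture()
  expect_error(find_decisions(fx$gs[0, ]), "empty|group_series")
})
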