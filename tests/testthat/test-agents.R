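test_that("initial states: speeds exactly zero, scatter, determinism", {
  cfg <- agent_config("all_vote", seed = 1L)
  s1 <- with_seed_init <- local({ set.seed(5); init_agents(cfg) })
  expect_true(all(s1$speed == 0))
  expect_length(s1$x, 10L)
  expect_true(all(s1$is_voter))
  expect_true(all(is.finite(s1$vote_angle)))

  cfg0 <- agent_config("copying", init_pos_sd = 0)
  s0 <- local({ set.seed(2); init_agents(cfg0) })
  expect_true(all(s0$x == 0) && all(s0$y == 0))

  a <- local({ set.seed(9); init_agents(cfg) })
  b <- local({ set.seed(9); init_agents(cfg) })
  expect_identical(a, b)
})

test_that("von Mises sampler matches closed-form moments", {
  set.seed(31)
  for (kappa in c(0.5, 4, 20)) {
    x <- rvonmises(4000, mu = 1.2, kappa = kappa)
    expect_true(all(x >= 0 & x < 2 * pi))
    expect_lt(abs(angle_diff(circular_mean(x), 1.2)), 0.12)
    a1 <- besselI(kappa, 1) / besselI(kappa, 0)   # E[resultant length]
    expect_lt(abs(resultant_length(x) - a1), 0.03)
  }
  set.seed(4)
  u <- rvonmises(2000, 0, 0)   # kappa = 0: uniform
  expect_lt(resultant_length(u), 0.06)
})

test_that("turn cap holds at every step and speeds stay in {0, sigma}", {
  cfg <- agent_config("sub_vote", speed_sigma = 1.4, seed = 77L)
  sim <- run_simulation(cfg)
  motion <- instantaneous_motion(sim$table)
  sp <- motion$speed_mps[is.finite(motion$speed_mps)]
  expect_true(all(abs(sp) < 1e-9 | abs(sp - 1.4) < 1e-9))
  for (id in unique(sim$table$individual_id)) {
    h <- sim$table$heading_rad[sim$table$individual_id == id]
    expect_true(all(abs(angle_diff(h[-1], h[-length(h)])) <= 0.75 + 1e-9))
  }
})

test_that("fixed point: moving consensus at the shared preference persists", {
  cfg <- agent_config("copying", n_agents = 4L, heading_wander_sd = 0,
                      target_direction_rad = 1, kappa = 4)
  st <- local({ set.seed(1); init_agents(cfg) })
  st$heading <- rep(1, 4)
  st$vote_angle <- rep(1, 4)       # shared preference equals the heading
  st$move_init_s <- rep(0, 4)      # everyone moving
  st2 <- step_agents(st, cfg, t = 5)
  expect_equal(st2$heading, rep(1, 4))
  expect_equal(st2$x, st$x + cos(1))   # advanced at sigma = 1 along heading
  expect_equal(st2$y, st$y + sin(1))
})

test_that("a mover turns toward its moving neighbours' mean by at most the cap", {
  cfg <- agent_config("copying", n_agents = 5L, heading_wander_sd = 0)
  st <- local({ set.seed(1); init_agents(cfg) })
  st$heading <- c(0, rep(2, 4))
  st$vote_angle <- c(NA_real_, rep(2, 4))  # focal has no preference pull
  st$move_init_s <- rep(0, 5)
  st2 <- step_agents(st, cfg, t = 1)
  expect_equal(st2$heading[1], 0.75)       # clamped turn toward 2
  # pre-initiation agents stay put
  st$move_init_s <- rep(100, 5)
  st$is_voter <- rep(FALSE, 5)
  cfg0 <- cfg; cfg0$heading_wander_sd <- 0
  st3 <- step_agents(st, cfg0, t = 1)
  expect_equal(st3$heading, st$heading)
  expect_true(all(st3$speed == 0))
  expect_equal(st3$x, st$x)
})

test_that("run_simulation is byte-deterministic under a fixed seed", {
  cfg <- agent_config("all_vote", seed = 123L)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
})

test_that("copying run: polar order rises from a dispersed baseline to ~1", {
  sim <- sim_fixture("copying", seed = 6L)
  gs <- group_series(sim$table)
  early <- mean(gs$polar_order[gs$time_s <= 40])
  late <- mean(gs$polar_order[gs$time_s >= 120])
  expect_lt(early, 0.75)
  expect_gt(late, 0.97)
})

test_that("all_vote run: decision parameter rises before group speed", {
  sim <- sim_fixture("all_vote", seed = 8L)
  gs <- group_series(sim$table)
  ref <- sim$truth$departure_direction_rad
  r <- decision_parameter(gs$mean_heading_rad, ref)
  t_dep <- sim$truth$t_departure_s
  # aligned well before departure, while still stationary
  pre <- gs$time_s > t_dep - 15 & gs$time_s <= t_dep - 5
  expect_gt(mean(r[pre], na.rm = TRUE), 0.9)
  expect_lt(mean(gs$mean_speed_mps[pre], na.rm = TRUE), 0.2)
})

test_that("sensor noise: identity at zero, position/heading separation, sd recovery", {
  sim <- sim_fixture("copying", seed = 12L, n_steps = 50L)
  expect_identical(as.data.frame(add_sensor_noise(sim$table, 0, 0, seed = 1)),
                   as.data.frame(sim$table))
  h_only <- add_sensor_noise(sim$table, 0, 0.2, seed = 2)
  expect_equal(h_only$x_m, sim$table$x_m)
  expect_false(isTRUE(all.equal(h_only$heading_rad, sim$table$heading_rad)))
  noisy <- add_sensor_noise(sim$table, 0.5, 0.1, seed = 3)
  expect_equal(sd(noisy$x_m - sim$table$x_m), 0.5, tolerance = 0.05)
  expect_equal(sd(angle_diff(noisy$heading_rad, sim$table$heading_rad)), 0.1,
               tolerance = 0.05)
  expect_error(add_sensor_noise(sim$table, -1, 0), "sds")
})

test_that("cohesion metrics flag split and intact groups", {
  sim <- sim_fixture("copying", seed = 14L, n_steps = 60L)
  cm <- cohesion_metrics(sim$table, split_distance = 50)
  expect_false(cm$split)
  expect_true(cm$consensus >= 0 && cm$consensus <= 1)
  # constructed split: two half-groups far apart at the final step
  df <- expand.grid(time_s = 1:2, individual_id = sprintf("i%d", 1:6),
                    stringsAsFactors = FALSE)
  df$x_m <- ifelse(match(df$individual_id, unique(df$individual_id)) <= 3, 0, 500)
  df$y_m <- 0; df$heading_rad <- 0
  expect_true(cohesion_metrics(trajectory_table(df), split_distance = 50)$split)
})

test_that("simulate_dataset: continuous day, correct event count, determinism", {
  ds <- simulate_dataset(agent_config("copying"), n_events = 3, seed = 2)
  expect_length(ds$truths, 3L)
  expect_equal(nrow(ds$table), 10 * (3 * 220 + 2 * 120))
  expect_equal(sort(unique(diff(sort(unique(ds$table$time_s))))), 1L)
  ds2 <- simulate_dataset(agent_config("copying"), n_events = 3, seed = 2)
  expect_identical(ds$table, ds2$table)
  # positions are continuous across block seams (no jumps while resting)
  one <- ds$table[ds$table$individual_id == "a01", ]
  one <- one[order(one$time_s), ]
  step <- sqrt(diff(one$x_m)^2 + diff(one$y_m)^2)
  expect_true(all(step <= 1 + 1e-9))
})

test_that("simulate_predictions errors when the pool is smaller than a dataset", {
  expect_error(simulate_predictions(agent_config("copying"), n_events = 5,
                                    n_decisions = 21), "pool")
})
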