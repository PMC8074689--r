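test_that("decision parameter endpoints and closed form", {
  expect_equal(decision_parameter(pi / 6, pi / 6), 1)
  expect_equal(decision_parameter(0, pi), 0)
  expect_equal(decision_parameter(0, pi / 2), sqrt(2) / 2)
  # vector-sum oracle on a coarse grid; closed-form |cos(d/2)| equivalence
  a1 <- seq(0, 2 * pi, length.out = 37)[-37]
  for (a in a1) {
    r <- decision_parameter(a, a1)
    oracle <- sqrt(((cos(a) + cos(a1)) / 2)^2 + ((sin(a) + sin(a1)) / 2)^2)
    expect_equal(r, oracle, tolerance = 1e-14)
    expect_equal(r, abs(cos((a - a1) / 2)), tolerance = 1e-12)
  }
})

test_that("decision parameter is symmetric and rotation invariant", {
  set.seed(2)
  a <- runif(50, 0, 2 * pi); b <- runif(50, 0, 2 * pi); rot <- runif(50, -9, 9)
  expect_equal(decision_parameter(a, b), decision_parameter(b, a))
  expect_equal(decision_parameter(wrap_angle(a + rot), wrap_angle(b + rot)),
               decision_parameter(a, b), tolerance = 1e-12)
})

test_that("cross-correlation recovers pure shifts with the stated sign convention", {
  z <- sharp_signal(280)
  n <- 240L
  for (k in c(-10L, -5L, -1L, 0L, 3L, 10L)) {
    # speed lags r by k: both series cut from one master, no edge padding
    r_series <- z[21:(20 + n)]
    speed <- z[(21 - k):(20 + n - k)]
    cc <- cross_correlate(data.frame(r = r_series, speed_mps = speed),
                          max_lag_s = 20)
    expect_equal(cc$corr_max_lag_s, -k, info = paste("shift", k))
  }
})

test_that("cross-correlation curve matches stats::ccf and the naive oracle", {
  set.seed(8)
  x <- rich_signal(150) + rnorm(150, 0, 0.05)
  y <- rev(rich_signal(150)) + rnorm(150, 0, 0.05)
  cc <- cross_correlate(data.frame(r = x, speed_mps = y), max_lag_s = 12)
  expect_equal(cc$corr, oracle_ccf(x, y, 12), tolerance = 1e-10)
  ref <- stats::ccf(x, y, lag.max = 12, plot = FALSE, demean = TRUE)
  expect_equal(cc$corr, as.vector(ref$acf), tolerance = 1e-10)
})

test_that("cross-correlation input contracts", {
  x <- rich_signal(60)
  expect_error(cross_correlate(data.frame(r = x, speed_mps = x),
                               max_lag_s = 40, clamp = FALSE), "2\\*max_lag")
  expect_error(cross_correlate(data.frame(r = rep(1, 60), speed_mps = x), 10),
               "zero-variance")
  cc <- cross_correlate(data.frame(r = x, speed_mps = x), max_lag_s = 10)
  expect_equal(cc$corr_max_lag_s, 0)
  expect_equal(cc$corr_max, 1, tolerance = 1e-12)
})

test_that("symmetry index: unit mass, mirror symmetry, antisymmetry under reversal", {
  lags <- -10:10
  corr <- numeric(21); corr[lags == -3] <- 1
  expect_equal(symmetry_index(list(lags_s = lags, corr = corr)), -1)
  sym_curve <- exp(-abs(lags) / 3)
  expect_equal(symmetry_index(list(lags_s = lags, corr = sym_curve)), 0)
  set.seed(4)
  corr2 <- runif(21, -1, 1)
  expect_equal(symmetry_index(list(lags_s = lags, corr = rev(corr2))),
               -symmetry_index(list(lags_s = lags, corr = corr2)))
  expect_error(symmetry_index(list(lags_s = 0:10, corr = runif(11))),
               "symmetric")
})

test_that("pooled bootstrap: degenerate case, coverage, determinism, shrinkage", {
  b0 <- pooled_bootstrap(rep(3.5, 10), n_boot = 100, seed = 1)
  expect_equal(b0$median, 3.5)
  expect_equal(b0$ci, c(3.5, 3.5))

  b1 <- pooled_bootstrap(1:21, n_boot = 1000, seed = 99)
  expect_lte(b1$ci[1], 11); expect_gte(b1$ci[2], 11)
  expect_identical(b1, pooled_bootstrap(1:21, n_boot = 1000, seed = 99))

  # direct independent bootstrap oracle under the same seed policy
  oracle <- local({
    set.seed(99)
    meds <- replicate(1000, median(sample(1:21, replace = TRUE)))
    unname(quantile(meds, c(0.025, 0.975)))
  })
  expect_equal(b1$ci, oracle)

  set.seed(123)
  w_small <- mean(replicate(20, diff(pooled_bootstrap(rnorm(21), 200,
                                                      sample.int(1e6, 1))$ci)))
  w_large <- mean(replicate(20, diff(pooled_bootstrap(rnorm(210), 200,
                                                      sample.int(1e6, 1))$ci)))
  expect_lt(w_large, w_small)
  expect_error(pooled_bootstrap(1:5, n_boot = 0), "n_boot")
})

test_that("one-sample t matches the textbook formula and stats::t.test", {
  v <- c(1, 2, 3)
  got <- one_sample_t(v, 0)
  expect_equal(got$t, mean(v) / (sd(v) / sqrt(3)))
  expect_equal(got$df, 2L)
  ref <- stats::t.test(v, mu = 0)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  eq <- one_sample_t(c(1, 2, 3, 2), 2)
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  expect_error(one_sample_t(rep(1, 4), 1), "zero variance")
})

test_that("decision curve: aligned group gives r = 1; departure-mode max reaches 1", {
  sim <- sim_fixture("all_vote", seed = 21L)
  gs <- group_series(sim$table)
  ev <- list(event_id = 1L, day_id = "sim",
             t_departure_s = sim$truth$t_departure_s,
             window = c(1L, 220L),
             departure_direction_rad = sim$truth$departure_direction_rad,
             destination_direction_rad = NA_real_,
             t_heading_cp_s = sim$truth$t_departure_s,
             stationary_ok = TRUE, excluded_reason = "none", truncated = FALSE)
  cu <- decision_curve(ev, gs, "departure")
  expect_true(attr(cu, "truncated"))   # pre-window larger than the run start
  expect_true(all(cu$r >= 0 & cu$r <= 1, na.rm = TRUE))
  post <- cu$r[cu$rel_time_s >= 0 & cu$rel_time_s <= 30]
  expect_gte(max(post, na.rm = TRUE), 0.99)
})
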