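# A heading trace with persistent structure: smooth random turns, so that
# windows have variance and shifted copies correlate near 1.
wavy_heading <- function(n, seed) {
  set.seed(seed)
  wrap_angle(cumsum(rnorm(n, 0, 0.25)))
}

test_that("dyad scoring recovers a constructed shift, antisymmetrically", {
  x <- wavy_heading(120, 1)
  lagged <- c(rep(x[1], 4), x[1:116])   # j follows i by 4 s
  sc <- dyad_lag_score(x, lagged)
  expect_gt(nrow(sc), 50)
  expect_gte(mean(sc$score_i == 1L), 0.9)
  sc_rev <- dyad_lag_score(lagged, x)
  expect_gte(mean(sc_rev$score_i == -1L), 0.9)
  merged <- merge(sc, sc_rev, by = "step")
  expect_true(all(merged$score_i.x == -merged$score_i.y))
})

test_that("identical series are neutral; uncorrelated noise is below threshold", {
  x <- wavy_heading(100, 2)
  expect_true(all(dyad_lag_score(x, x)$score_i == 0L))
  set.seed(3)
  y <- runif(100, 0, 2 * pi)
  scores <- dyad_lag_score(x, y)$score_i
  # short windows let ~10% of noise steps clear the 0.9 gate by chance
  expect_gte(mean(scores == 0L), 0.8)
  expect_lt(abs(mean(scores)), 0.2)   # no systematic leader among noise
  expect_error(dyad_lag_score(x[1:10], y[1:10], window_s = 15), "window")
})

test_that("leadership matrix counts scored steps into (leader, follower) cells", {
  n <- 240
  lead <- wavy_heading(n, 4)
  foll <- c(rep(lead[1], 5), lead[1:(n - 5)])
  third <- wavy_heading(n, 5)
  df <- rbind(
    data.frame(time_s = 1:n, individual_id = "A", x_m = 0, y_m = 0, heading_rad = lead),
    data.frame(time_s = 1:n, individual_id = "B", x_m = 1, y_m = 0, heading_rad = foll),
    data.frame(time_s = 1:n, individual_id = "C", x_m = 2, y_m = 0, heading_rad = third)
  )
  tab <- trajectory_table(df)
  ev <- list(list(event_id = 1L, day_id = "day1", t_departure_s = 120L,
                  window = c(20L, 220L), excluded_reason = "none"))
  M <- build_matrix(ev, tab, phase = "departure", config = run_config())
  expect_equal(dim(M), c(3L, 3L))
  expect_true(all(diag(M) == 0L))
  expect_gt(M["A", "B"], M["B", "A"])          # A leads B
  expect_gt(M["A", "B"], 20L)
  M2 <- build_matrix(ev, tab, phase = "travelling", config = run_config())
  expect_gt(M2["A", "B"], M2["B", "A"])
})

test_that("normDS: total order, symmetry, and hand-computed 3-way tournament", {
  # perfect linear dominance among 4
  M <- matrix(0L, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  M[upper.tri(M)] <- 10L
  nd <- norm_david_score(M)
  expect_true(all(diff(nd) < 0))
  sym <- matrix(5L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(sym) <- 0L
  expect_true(all(abs(norm_david_score(sym) - norm_david_score(sym)[1]) < 1e-12))
  set.seed(6)
  W <- matrix(rpois(9, 5), 3, 3, dimnames = list(c("x","y","z"), c("x","y","z")))
  diag(W) <- 0L
  expect_equal(unname(norm_david_score(W)), unname(oracle_normds(W)),
               tolerance = 1e-12)
  expect_warning(norm_david_score(matrix(0L, 3, 3)), "all-zero")
})

test_that("triangle transitivity: hierarchy, cycle, and null behaviour", {
  for (N in c(5L, 8L, 10L)) {
    M <- matrix(0L, N, N)
    M[upper.tri(M)] <- 20L
    tt <- triangle_transitivity(M, n_perm = 50, seed = 1)
    expect_equal(tt$t_tri, 1)
    expect_equal(tt$n_triangles, choose(N, 3))
  }
  cyc <- matrix(0L, 3, 3)
  cyc[1, 2] <- 20L; cyc[2, 3] <- 20L; cyc[3, 1] <- 20L
  expect_equal(triangle_transitivity(cyc, n_perm = 50, seed = 1)$t_tri, -3)
  # random tournaments: mean t_tri near 0
  set.seed(8)
  vals <- replicate(40, {
    N <- 6L
    M <- matrix(0L, N, N)
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      if (runif(1) < 0.5) M[i, j] <- 20L else M[j, i] <- 20L
    }
    .t <- triangle_transitivity(M, n_perm = 1, seed = 1)$t_tri
  })
  expect_lt(abs(mean(vals)), 0.3)
  # undecided dyads (below min_steps) excluded
  weak <- matrix(2L, 3, 3); diag(weak) <- 0L
  expect_true(is.na(triangle_transitivity(weak, min_steps = 10)$t_tri))
})

test_that("directional consistency: endpoints and the worked two-dyad example", {
  one_sided <- matrix(0L, 3, 3); one_sided[1, 2] <- 7L; one_sided[1, 3] <- 3L
  expect_equal(directional_consistency(one_sided, n_perm = 50, seed = 1)$dc, 1)
  balanced <- matrix(4L, 3, 3); diag(balanced) <- 0L
  expect_equal(directional_consistency(balanced, n_perm = 50, seed = 1)$dc, 0)
  # dyads (3,1) and (2,2): dc = (2 + 0) / (4 + 4) = 0.25
  M <- matrix(0L, 3, 3)
  M[1, 2] <- 3L; M[2, 1] <- 1L
  M[1, 3] <- 2L; M[3, 1] <- 2L
  expect_equal(directional_consistency(M, n_perm = 50, seed = 1)$dc, 0.25)
  # relabeling invariance
  p <- c(3, 1, 2)
  expect_equal(directional_consistency(M[p, p], n_perm = 10, seed = 1)$dc, 0.25)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(10)
  pvals <- replicate(60, {
    M <- matrix(0L, 4, 4)
    for (i in 1:3) for (j in (i + 1):4) {
      w <- rbinom(1, 20, 0.5)
      M[i, j] <- w; M[j, i] <- 20L - w
    }
    directional_consistency(M, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(min(pvals), 0)
  expect_lte(max(pvals), 1)
  # under the null p should not pile up near 0: KS-style coarse check
  expect_lt(abs(mean(pvals) - 0.5), 0.12)
  expect_gt(mean(pvals > 0.5), 0.3)
})
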