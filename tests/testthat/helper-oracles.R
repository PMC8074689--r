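# Independent oracles kept deliberately naive: brute force and closed form,
# no shared code with the implementation they check.

# Exhaustive penalized segmentation with 0..max_splits change-points.
# cost_fn(a, b) must match the implementation's segment cost family.
oracle_segment <- function(x, penalty, max_splits = 2L, min_seg = 2L,
                           target = "mean") {
  n <- length(x)
  cost <- function(a, b) {
    seg <- x[a:b]
    if (target == "mean") {
      sum((seg - mean(seg))^2)
    } else {
      m <- length(seg)
      v <- max(mean(seg^2) - mean(seg)^2, 1e-8)
      m * (log(2 * pi * v) + 1)
    }
  }
  best <- list(cost = cost(1, n), cps = integer(0))
  if (max_splits >= 1L) {
    for (c1 in seq(min_seg, n - min_seg)) {
      v <- cost(1, c1) + cost(c1 + 1, n) + penalty
      if (v < best$cost) best <- list(cost = v, cps = c1)
    }
  }
  if (max_splits >= 2L) {
    for (c1 in seq(min_seg, n - 2L * min_seg)) {
      left <- cost(1, c1)
      for (c2 in seq(c1 + min_seg, n - min_seg)) {
        v <- left + cost(c1 + 1, c2) + cost(c2 + 1, n) + 2 * penalty
        if (v < best$cost) best <- list(cost = v, cps = c(c1, c2))
      }
    }
  }
  best
}

# Vector-sum circular mean / resultant, written out longhand.
oracle_circ <- function(angles) {
  sx <- 0; sy <- 0
  for (a in angles) {
    sx <- sx + cos(a)
    sy <- sy + sin(a)
  }
  list(mean = atan2(sy, sx) %% (2 * pi),
       rho = sqrt(sx^2 + sy^2) / length(angles))
}

# Full lag-scan sample cross-correlation, classic convention
# (full-series means/sds, divisor n); corr[k] = cor(x[t+k], y[t]).
oracle_ccf <- function(x, y, L) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
  vapply(-L:L, function(k) {
    s <- 0
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) s <- s + (x[t + k] - mx) * (y[t] - my)
    }
    s / (n * sx * sy)
  }, 0)
}

# Textbook David's score with the dyadic correction, element by element.
oracle_normds <- function(M) {
  N <- nrow(M)
  D <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    if (i == j) next
    nij <- M[i, j] + M[j, i]
    if (nij > 0) {
      P <- M[i, j] / nij
      D[i, j] <- P - (P - 0.5) / (nij + 1)
    }
  }
  w <- rowSums(D); l <- colSums(D)
  w2 <- sapply(1:N, function(i) sum(D[i, ] * w))
  l2 <- sapply(1:N, function(i) sum(D[, i] * l))
  DS <- w + w2 - l - l2
  (DS + N * (N - 1) / 2) / N
}

# A deterministic smooth signal (sigmoid plus bumps) for ccf-curve tests.
rich_signal <- function(n, center = n / 2) {
  t <- seq_len(n)
  1 / (1 + exp(-(t - center) / 4)) + 0.15 * sin(t / 7) + 0.05 * cos(t / 3)
}

# A signal with sharp autocorrelation for exact lag-recovery tests: the
# classic ccf convention tapers values by (n - |k|)/n, so the argmax is only
# exactly the true shift when the signal decorrelates fast.
sharp_signal <- function(n, seed = 1) {
  set.seed(seed)
  rnorm(n)
}

# Shared small simulated fixture (computed once per test run).
sim_fixture <- local({
  cache <- new.env()
  function(mechanism = "copying", seed = 42L, ...) {
    key <- paste(mechanism, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- run_simulation(
        agent_config(mechanism = mechanism, seed = seed, ...))
    }
    cache[[key]]
  }
})
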