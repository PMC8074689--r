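# Leader-follower structure from pairwise time-lag heading correlations:
# per-second dyad scores, the summed leadership matrix, normalized David's
# score ranks, triangle transitivity and directional consistency with
# permutation tests.

# Rolling Pearson correlation between x and y over windows of length w
# ending at each index; returns NA where the window is incomplete or
# either window has zero variance.
.roll_cor <- function(x, y, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x^2)); cyy <- c(0, cumsum(y^2))
  cxy <- c(0, cumsum(x * y))
  t <- w:n
  sx <- cx[t + 1] - cx[t + 1 - w]; sy <- cy[t + 1] - cy[t + 1 - w]
  sxx <- cxx[t + 1] - cxx[t + 1 - w]; syy <- cyy[t + 1] - cyy[t + 1 - w]
  sxy <- cxy[t + 1] - cxy[t + 1 - w]
  vx <- sxx - sx^2 / w; vy <- syy - sy^2 / w
  cv <- sxy - sx * sy / w
  r <- rep(NA_real_, length(t))
  okv <- vx > 1e-12 & vy > 1e-12
  r[okv] <- cv[okv] / sqrt(vx[okv] * vy[okv])
  out[t] <- r
  out
}

#' Per-step leader/follower scores for one dyad
#'
#' At each step the trailing `window_s`-second windows of the two
#' individuals' unwrapped headings are correlated across integer shifts in
#' `[-max_shift_s, max_shift_s]`.  If the best correlation is below
#' `threshold`, or is best at shift 0, the step is neutral (0/0); otherwise
#' the individual whose heading changes come first scores +1 and the other
#' -1.  Ties across shifts go to the smallest `|shift|`; a tie between a
#' positive and negative shift of equal magnitude is neutral.
#'
#' @param heading_i,heading_j aligned heading series, radians.
#' @param window_s correlation window length (default 15 samples).
#' @param max_shift_s maximum shift (default 10 samples).
#' @param threshold minimum correlation to score (default 0.9).
#' @return data.frame `step` (index into the series), `score_i` in
#'   `{-1, 0, 1}`; `score_j = -score_i` always.  Steps whose windows leave
#'   the series or have zero variance are absent.
#' @export
dyad_lag_score <- function(heading_i, heading_j, window_s = 15L,
                           max_shift_s = 10L, threshold = 0.9) {
  n <- length(heading_i)
  if (length(heading_j) != n) stop("dyad_lag_score: series length mismatch")
  if (window_s > n) stop("dyad_lag_score: window longer than series")
  x <- unwrap_angle(heading_i)
  y <- unwrap_angle(heading_j)
  shifts <- seq.int(-max_shift_s, max_shift_s)
  # corr_mat[s, t]: windows of x ending at t vs windows of y ending at t+s.
  # Positive best shift = j's future matches i's present = i leads.
  corr_mat <- matrix(NA_real_, length(shifts), n)
  for (si in seq_along(shifts)) {
    s <- shifts[si]
    if (s >= 0) {
      yn <- c(y[(1 + s):n], rep(NA, s))
    } else {
      yn <- c(rep(NA, -s), y[1:(n + s)])
    }
    # windows containing NA are invalid; mask via finite check afterwards
    ok <- !is.na(yn)
    yl <- ifelse(ok, yn, 0)
    rc <- .roll_cor(x, yl, window_s)
    bad_tail <- which(!ok)
    if (length(bad_tail)) {
      for (b in bad_tail) {
        lo <- b; hi <- min(b + window_s - 1L, n)
        rc[lo:hi] <- NA_real_
      }
    }
    corr_mat[si, ] <- rc
  }
  t_lo <- window_s + max_shift_s
  t_hi <- n - max_shift_s
  if (t_lo > t_hi) stop("dyad_lag_score: series too short for window + shift")
  steps <- t_lo:t_hi
  score <- integer(length(steps))
  for (k in seq_along(steps)) {
    col <- corr_mat[, steps[k]]
    if (all(is.na(col))) { score[k] <- NA_integer_; next }
    mx <- max(col, na.rm = TRUE)
    if (mx < threshold) { score[k] <- 0L; next }
    best <- shifts[which(col >= mx - 1e-12)]
    best <- best[order(abs(best))]
    if (abs(best[1L]) %in% abs(best[-1L]) || best[1L] == 0L) {
      score[k] <- 0L
    } else {
      score[k] <- if (best[1L] > 0L) 1L else -1L
    }
  }
  ok <- !is.na(score)
  data.frame(step = steps[ok], score_i = score[ok])
}

#' Build the summed leadership matrix over events
#'
#' For every retained event and every dyad, per-second scores are computed
#' on the phase window (`departure`: the `window_pre_s` seconds up to the
#' departure; `travelling`: the `window_post_s` seconds after it) and each
#' +1 step increments the (leader, follower) cell.
#'
#' @param events retained `decision_event` list (see [retained_events()]).
#' @param table the [trajectory_table()].
#' @param phase `"departure"` or `"travelling"`.
#' @param config a [run_config()].
#' @return a `leadership_matrix`: integer matrix with individual ids as
#'   dimnames and attribute `phase`; zero diagonal.
#' @export
build_matrix <- function(events, table, phase = c("departure", "travelling"),
                         config = run_config()) {
  phase <- match.arg(phase)
  stopifnot(inherits(table, "trajectory_table"))
  if (!length(events)) stop("build_matrix: no events")
  ids <- sort(unique(table$individual_id))
  M <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (ev in events) {
    w <- if (phase == "departure") {
      c(ev$t_departure_s - config$window_pre_s, ev$t_departure_s)
    } else {
      c(ev$t_departure_s, ev$t_departure_s + config$window_post_s)
    }
    sub <- table[table$day_id == ev$day_id &
                   table$time_s >= w[1L] & table$time_s <= w[2L], , drop = FALSE]
    grid <- sort(unique(sub$time_s))
    if (length(grid) < config$leader_window_s + 2L * config$leader_max_shift_s) next
    H <- sapply(ids, function(id) {
      sub$heading_rad[match(paste(id, grid), paste(sub$individual_id, sub$time_s))]
    })
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a) next
        hi <- H[, a]; hj <- H[, b]
        if (anyNA(hi) || anyNA(hj)) next
        sc <- dyad_lag_score(hi, hj, config$leader_window_s,
                             config$leader_max_shift_s,
                             config$leader_threshold)
        M[a, b] <- M[a, b] + sum(sc$score_i == 1L)
        M[b, a] <- M[b, a] + sum(sc$score_i == -1L)
      }
    }
  }
  structure(M, phase = phase, class = c("leadership_matrix", class(M)))
}

#' Normalized David's scores
#'
#' David's score from dyadic win proportions with the standard dyadic
#' sample-size correction `Dij = Pij - (Pij - 0.5)/(nij + 1)`, normalized
#' as `(DS + N(N-1)/2) / N`.  An all-zero matrix yields equal scores
#' (degenerate, with a warning).
#'
#' @param matrix a [build_matrix()] result or any square count matrix with
#'   dimnames.
#' @return named numeric vector of normDS, descending order = leadership
#'   rank.
#' @export
norm_david_score <- function(matrix) {
  M <- unclass(matrix)
  N <- nrow(M)
  if (N < 2L) stop("norm_david_score: need >= 2 individuals")
  if (all(M == 0)) warning("norm_david_score: all-zero matrix; scores degenerate")
  nij <- M + t(M)
  P <- matrix(0, N, N, dimnames = dimnames(M))
  pos <- nij > 0
  P[pos] <- M[pos] / nij[pos]
  D <- P
  D[pos] <- P[pos] - (P[pos] - 0.5) / (nij[pos] + 1)
  diag(D) <- 0
  w <- rowSums(D)
  l <- colSums(D)
  w2 <- as.vector(D %*% w)
  l2 <- as.vector(t(D) %*% l)
  DS <- w + w2 - l - l2
  normDS <- (DS + N * (N - 1) / 2) / N
  names(normDS) <- rownames(M)
  normDS
}

# Binarize a leadership matrix to dominant dyad directions; dyads with
# fewer than min_steps decided interactions or exact ties are dropped.
# Returns a data.frame of directed pairs (winner, loser indices).
.dominant_dyads <- function(M, min_steps) {
  N <- nrow(M)
  out <- list()
  for (a in seq_len(N - 1L)) {
    for (b in (a + 1L):N) {
      tot <- M[a, b] + M[b, a]
      if (tot < min_steps || M[a, b] == M[b, a]) next
      if (M[a, b] > M[b, a]) {
        out[[length(out) + 1L]] <- c(a, b)
      } else {
        out[[length(out) + 1L]] <- c(b, a)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

.ttri_from_dyads <- function(dyads, N) {
  dom <- matrix(NA, N, N)
  for (r in seq_len(nrow(dyads))) {
    dom[dyads[r, 1L], dyads[r, 2L]] <- TRUE
    dom[dyads[r, 2L], dyads[r, 1L]] <- FALSE
  }
  n_tri <- 0L; n_trans <- 0L
  if (N >= 3L) {
    for (i in seq_len(N - 2L)) for (j in (i + 1L):(N - 1L)) for (k in (j + 1L):N) {
      if (is.na(dom[i, j]) || is.na(dom[j, k]) || is.na(dom[i, k])) next
      n_tri <- n_tri + 1L
      # a 3-cycle has each node with exactly one win inside the triangle
      wins <- c(dom[i, j] + dom[i, k], (!dom[i, j]) + dom[j, k],
                (!dom[i, k]) + (!dom[j, k]))
      if (any(wins == 2L)) n_trans <- n_trans + 1L
    }
  }
  if (n_tri == 0L) return(c(NA_real_, 0))
  c(4 * (n_trans / n_tri - 0.75), n_tri)
}

#' Triangle transitivity of the leadership network
#'
#' Each dyad is binarized to its dominant direction; `P_t` is the
#' proportion of transitive triangles among fully-decided triangles and
#' `t_tri = 4 (P_t - 0.75)` (1 = perfect linear hierarchy, 0 = random
#' expectation).  The permutation p-value re-orients every decided dyad at
#' random and is the one-sided probability of a transitivity at least as
#' large.
#'
#' @param matrix a [build_matrix()] result.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param min_steps minimum decided steps per dyad (default 10).
#' @return list `t_tri`, `p`, `n_triangles`; `t_tri` is `NA` when no
#'   complete triangle exists.
#' @export
triangle_transitivity <- function(matrix, n_perm = 1000L, seed = NULL,
                                  min_steps = 10L) {
  M <- unclass(matrix)
  N <- nrow(M)
  if (N < 3L) stop("triangle_transitivity: need >= 3 individuals")
  dyads <- .dominant_dyads(M, min_steps)
  if (is.null(dyads)) return(list(t_tri = NA_real_, p = NA_real_, n_triangles = 0L))
  obs <- .ttri_from_dyads(dyads, N)
  if (is.na(obs[1L])) return(list(t_tri = NA_real_, p = NA_real_, n_triangles = 0L))
  perm_t <- with_rng(seed, {
    vapply(seq_len(n_perm), function(b) {
      flip <- stats::runif(nrow(dyads)) < 0.5
      d2 <- dyads
      d2[flip, ] <- d2[flip, c(2L, 1L), drop = FALSE]
      .ttri_from_dyads(d2, N)[1L]
    }, 0)
  })
  p <- (1 + sum(perm_t >= obs[1L] - 1e-12)) / (n_perm + 1)
  list(t_tri = obs[1L], p = p, n_triangles = as.integer(obs[2L]))
}

#' Directional consistency of the leadership network
#'
#' `dc = sum(H - L) / sum(H + L)` over dyads with interactions, where H/L
#' are the larger/smaller of the two directed counts: 1 when every pair's
#' leading relation is fully one-sided, 0 when all are balanced.  The
#' permutation p-value redirects every interaction independently with
#' probability 1/2 (one-sided, large dc = consistent).
#'
#' @param matrix a [build_matrix()] result.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list `dc`, `p`, `n_interactions`.
#' @export
directional_consistency <- function(matrix, n_perm = 1000L, seed = NULL) {
  M <- unclass(matrix)
  N <- nrow(M)
  up <- which(upper.tri(M))
  wij <- M[upper.tri(M)]
  wji <- t(M)[upper.tri(M)]
  tot <- wij + wji
  use <- tot > 0
  if (!any(use)) return(list(dc = NA_real_, p = NA_real_, n_interactions = 0L))
  dc_of <- function(a, b) sum(pmax(a, b) - pmin(a, b)) / sum(a + b)
  obs <- dc_of(wij[use], wji[use])
  perm <- with_rng(seed, {
    vapply(seq_len(n_perm), function(bb) {
      a2 <- stats::rbinom(sum(use), tot[use], 0.5)
      dc_of(a2, tot[use] - a2)
    }, 0)
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  list(dc = obs, p = p, n_interactions = sum(tot[use]))
}
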