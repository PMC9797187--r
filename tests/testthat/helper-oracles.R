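# Independent brute-force oracles used across the suite. These stay
# deliberately naive (per-pixel scans, exhaustive enumeration, O(n^2)
# loops) so they share no code with the implementation paths they check.

planted7 <- default_planted_borders()

# per-pixel four-direction scan: enclosed iff a line pixel exists
# strictly left, right, above and below
oracle_enclosure <- function(outline) {
  n <- nrow(outline); m <- ncol(outline)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (outline[i, j]) next
      out[i, j] <- any(outline[i, seq_len(j - 1)]) &&
        any(outline[i, seq.int(j + 1, m)[j < m]]) &&
        any(outline[seq_len(i - 1), j]) &&
        any(outline[seq.int(i + 1, n)[i < n], j])
    }
  }
  out
}

# frequency-count mode with lowest-label tie break
oracle_mode <- function(column) {
  tab <- table(column)
  lab <- as.integer(names(tab))
  cand <- lab[tab == max(tab)]
  min(cand)
}

# direct definition of circular transitions
oracle_transitions <- function(row) {
  n <- length(row)
  out <- integer(0)
  for (e in 0:(n - 1)) {
    prev <- if (e == 0) row[n] else row[e]
    if (row[e + 1] != prev) out <- c(out, e)
  }
  out
}

# lag-by-lag cross-correlation and shift pick, sharing no FFT code
oracle_shift <- function(rA, rB, bandsA, bandsB) {
  n <- length(rA)
  K <- bandsA$n_classes
  a <- row_to_unit_circle(rA, bandsA)
  b <- row_to_unit_circle(rB, bandsB)
  cc <- vapply(0:(n - 1), function(s) {
    idx <- ((0:(n - 1) + s) %% n) + 1
    sum(a$x * b$x[idx] + a$y * b$y[idx])
  }, numeric(1))
  tol <- 1e-9 * max(1, abs(max(cc)))
  cand <- which(cc >= max(cc) - tol) - 1
  tp <- n / K
  f <- cand %% tp
  f <- ifelse(f > tp / 2, f - tp, f)
  s <- round(f)
  P <- round(tp)
  s <- ((s + P) %% P)
  s <- ifelse(s > P / 2, s - P, s)
  as.integer(s[order(abs(s), s)][1])
}

# exact two-sided Fisher p for an r x 2 table by full enumeration of
# tables with fixed margins (multivariate hypergeometric)
oracle_fisher_rx2 <- function(tab) {
  rows <- rowSums(tab)
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  logp <- function(a) sum(lchoose(rows, a)) - lchoose(N, c1)
  p_obs <- logp(tab[, 1])
  total <- 0
  enum <- function(i, left, acc) {
    if (i == length(rows)) {
      if (left <= rows[i]) {
        lp <- logp(c(acc, left))
        if (lp <= p_obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    for (a in 0:min(rows[i], left)) enum(i + 1, left - a, c(acc, a))
  }
  enum(1, c1, integer(0))
  min(total, 1)
}

# circular median by dense grid search over candidate angles
oracle_circular_median <- function(h) {
  grid <- seq(0, 1 - 1e-4, by = 1e-4)
  cost <- vapply(grid, function(x) sum(circular_distance(x, h)), numeric(1))
  grid[which.min(cost)]
}

# closest-first disjoint merging of two border sets, written as plain
# loops over a distance table (mirrors the documented crowded-region
# threshold-halving rule)
oracle_merge <- function(a, b, thr) {
  d <- outer(a, b, circular_distance)
  cand <- d < thr
  conflict <- outer(rowSums(cand) > 1, colSums(cand) > 1, "|")
  lim <- matrix(thr, length(a), length(b))
  lim[conflict] <- thr / 2
  used_a <- rep(FALSE, length(a)); used_b <- rep(FALSE, length(b))
  merged <- numeric(0)
  repeat {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) {
      if (!used_a[i] && !used_b[j] && d[i, j] < lim[i, j] && d[i, j] < best) {
        best <- d[i, j]; bi <- i; bj <- j
      }
    }
    if (bi == 0) break
    used_a[bi] <- TRUE; used_b[bj] <- TRUE
    merged <- c(merged, circular_weighted_mean(c(a[bi], b[bj])))
  }
  sort(c(merged, a[!used_a], b[!used_b]))
}

max_planted_error <- function(positions, planted) {
  max(vapply(positions, function(p) min(circular_distance(p, planted)),
             numeric(1)))
}
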