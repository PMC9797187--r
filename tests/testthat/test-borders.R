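test_that("column mode follows the stated tie rule and the counting oracle", {
  expect_equal(column_mode(rep(3L, 60)), 3L)
  expect_equal(column_mode(c(rep(1L, 30), rep(4L, 30))), 1L) # tie to lowest
  expect_error(column_mode(integer(0)), "empty")
  set.seed(31)
  for (i in 1:200) {
    col <- sample(0:6, sample(3:60, 1), replace = TRUE)
    expect_identical(column_mode(col), oracle_mode(col))
  }
})

test_that("transition detection closes the circle and matches the oracle", {
  expect_length(find_transitions(rep(2L, 100)), 0)
  expect_equal(find_transitions(c(rep(0L, 50), rep(1L, 50))), c(0L, 50L))
  set.seed(32)
  for (i in 1:100) {
    row <- sample(0:4, sample(5:60, 1), replace = TRUE)
    expect_identical(find_transitions(row), oracle_transitions(row))
  }
})

test_that("no circular row over a 3-letter alphabet has exactly one transition", {
  # exhaustive enumeration: with the circle closed, a lone transition
  # is impossible (you must come back to where you started)
  for (len in 3:6) {
    grid <- expand.grid(rep(list(0:2), len))
    counts <- apply(grid, 1, function(r) length(find_transitions(as.integer(r))))
    expect_false(any(counts == 1))
  }
})

test_that("transition accumulation conserves counts and smoothing preserves mass", {
  rows <- list(c(rep(0L, 50), rep(1L, 50)), c(rep(0L, 50), rep(1L, 50)))
  tc <- accumulate_transition_counts(rep(rows, 5))
  expect_equal(sort(tc$raw[tc$raw > 0]), c(10L, 10L))
  set.seed(33)
  rws <- lapply(1:20, function(i) sample(0:3, 60, replace = TRUE))
  tc2 <- accumulate_transition_counts(rws)
  expect_equal(sum(tc2$raw),
               sum(vapply(rws, function(r) length(find_transitions(r)), integer(1))))
  expect_lt(abs(sum(tc2$smoothed) - sum(tc2$raw)), 1e-9)
  expect_error(accumulate_transition_counts(list(rep(0L, 10), rep(0L, 12))),
               "bins")
})

test_that("peak detection finds synthetic bumps and rejects flat signals", {
  v <- rep(0, 100); v[30 + (-2:2)] <- c(2, 5, 9, 5, 2) # apex at edge 29
  pk <- detect_peaks(v)
  expect_equal(pk$indices, 29L)
  expect_equal(detect_peaks(rep(4, 100))$n_borders, 0L)
  # 7 well-separated bumps, one straddling the wrap
  centers <- c(3, 17, 31, 45, 59, 73, 95)
  v7 <- rep(0, 100)
  for (c0 in centers) {
    for (d in -2:2) v7[(c0 + d) %% 100 + 1] <- max(v7[(c0 + d) %% 100 + 1],
                                                   8 - 3 * abs(d) + c0 %% 3)
  }
  pk7 <- detect_peaks(v7)
  expect_equal(pk7$n_borders, 7L)
  expect_true(all(vapply(pk7$indices, function(i)
    min(abs(i - centers)) <= 1, logical(1))))
})

test_that("prototypes are reciprocal-weighted circular means of their interval", {
  n <- 100
  raw <- rep(3L, n)
  tc <- structure(list(n_bins = n, raw = raw, smoothed = raw, sigma = 1.5,
                       n_rows = 1L), class = "transition_count")
  borders <- structure(list(positions = c(0.2, 0.4, 0.9), n_borders = 3L,
                            n_bins = n), class = "border_estimate")
  pr <- compute_prototypes(borders, tc)
  # uniform weights on [0.2, 0.4) put the prototype at the interval middle
  expect_lt(circular_distance(pr$prototype[1], 0.3), 1e-6)
  # wrap category [0.9, 0.2): circular mean of member bins is 0.05
  expect_lt(circular_distance(pr$prototype[3], 0.05), 1e-6)
  # raising counts near the edges pulls the prototype toward the middle
  raw2 <- raw
  raw2[21:25] <- 300L # heavy transition mass at the left edge of [0.2, 0.4)
  tc2 <- structure(list(n_bins = n, raw = raw2, smoothed = raw2, sigma = 1.5,
                        n_rows = 1L), class = "transition_count")
  pr2 <- compute_prototypes(borders, tc2)
  expect_gt(pr2$prototype[1], pr$prototype[1])
  # prototype color is the spectrum color of the prototype hue
  expect_equal(unname(as.numeric(pr[1, c("r", "g", "b")])),
               as.numeric(hue_to_rgb(pr$prototype[1])))
})

test_that("unit-circle row coordinates sit on the circle at band-center angles", {
  bands <- make_uniform_bands(5, 0.1)
  row <- sample(0:4, 60, replace = TRUE)
  cc <- row_to_unit_circle(row, bands)
  expect_equal(cc$x^2 + cc$y^2, rep(1, 60))
  i <- 17
  expect_equal(cc$x[i], cos(2 * pi * bands$centers[row[i] + 1]))
  expect_equal(cc$y[i], sin(2 * pi * bands$centers[row[i] + 1]))
  row0 <- rep(0L, 60)
  b0 <- make_uniform_bands(4, 0)
  cc0 <- row_to_unit_circle(row0, b0)
  expect_true(all(cc0$x == 1) && all(cc0$y == 0))
  expect_error(row_to_unit_circle(c(0L, 9L), bands), "range")
})

test_that("optimal circular shift matches its brute-force oracle", {
  bands <- make_uniform_bands(7, 0)
  set.seed(34)
  for (i in 1:30) {
    rA <- sample(0:6, 100, replace = TRUE)
    rB <- sample(0:6, 100, replace = TRUE)
    expect_identical(optimal_circular_shift(rA, rB, bands, bands),
                     oracle_shift(rA, rB, bands, bands))
  }
  r <- simulate_row(continuous_responder(0), make_uniform_bands(7, 0.001),
                    eval_grid(100, 1))
  rot <- function(v, k) c(utils::tail(v, k), utils::head(v, length(v) - k))
  expect_equal(optimal_circular_shift(r, r), 0L)
  expect_equal(optimal_circular_shift(r$mode_row, rot(r$mode_row, 3),
                                      r$bands, r$bands), 3L)
  # a 10-bin rotation at K = 7 reports its alignment residue -4
  expect_equal(optimal_circular_shift(r$mode_row, rot(r$mode_row, 10),
                                      r$bands, r$bands), -4L)
})

test_that("shift histograms, Fisher comparison and overlap behave on known input", {
  grid <- eval_grid(100, 5)
  rows <- lapply(1:6, function(i)
    simulate_row(categorical_responder(planted7), make_uniform_bands(7, 0.01 * i),
                 grid, seed = i))
  h <- shift_distribution(rows)
  expect_equal(sum(h$signed_counts), choose(6, 2))
  expect_equal(sum(h$abs_counts), choose(6, 2))
  expect_equal(h$period, 14)
  hs <- shift_distribution(rep(rows[1], 4))
  expect_true(all(hs$shifts == 0))
  expect_equal(fisher_exact_table(c(5, 1), c(5, 1))$p_value, 1)
  ft <- fisher_exact_table(c(5, 1), c(1, 5))
  expect_equal(ft$method, "exact")
  expect_equal(ft$p_value, 0.08008, tolerance = 1e-3)
  expect_error(fisher_exact_table(c(-1, 2), c(1, 1)), "nonnegative")
  expect_equal(distribution_overlap(c(1, 1), c(1, 1)), 100)
  expect_equal(distribution_overlap(c(1, 0), c(0, 1)), 0)
  expect_equal(distribution_overlap(c(0.5, 0.5) * 10, c(0.8, 0.2) * 10), 70)
})

test_that("exact Fisher p-values agree with full enumeration on random tables", {
  set.seed(35)
  for (i in 1:25) {
    tab <- matrix(rpois(2 * sample(2:4, 1), 3), ncol = 2)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || any(colSums(tab) == 0)) next
    p_impl <- fisher_exact_table(tab[, 1], tab[, 2])$p_value
    expect_equal(p_impl, oracle_fisher_rx2(tab), tolerance = 1e-7)
  }
})

test_that("Monte-Carlo Fisher agrees with the exact path within 3 SE", {
  set.seed(36)
  tab <- matrix(c(8, 3, 2, 7, 5, 5), ncol = 2)
  exact <- fisher_exact_table(tab[, 1], tab[, 2])$p_value
  mc <- fisher_exact_table(tab[, 1], tab[, 2], enumeration_cap = 1, n_mc = 4e4)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p_value - exact), 3 * mc$se + 1e-4)
})
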