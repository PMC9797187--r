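test_that("category bands sit inside their borders with the 5%/10% rule", {
  bs <- border_set((0:6) / 7)
  cb <- bands_from_borders(bs)
  cl <- cb$classes[[1]] # category [0, 1/7], span 1/7
  s <- 1 / 7
  expect_equal(cl$left, c(0.05, 0.15) * s, tolerance = 1e-12)
  expect_equal(cl$right, c(1 / 7 - 0.15 * s, 1 / 7 - 0.05 * s),
               tolerance = 1e-12)
  # bands never touch the borders, and narrower categories have
  # narrower bands
  bs2 <- border_set(c(0.0, 0.1, 0.3, 0.5, 0.6, 0.8, 0.9))
  cb2 <- bands_from_borders(bs2)
  for (cl in cb2$classes) {
    expect_gt(cl$left[1], 0)
    expect_equal(diff(cl$left), 0.1 * cl$span)
  }
  spans <- vapply(cb2$classes, function(cl) cl$span, numeric(1))
  widths <- vapply(cb2$classes, function(cl) diff(cl$left), numeric(1))
  expect_equal(widths, 0.1 * spans, tolerance = 1e-12)
  expect_error(bands_from_borders(border_set(c(0.1, 0.105, 0.3, 0.5))),
               "degenerate")
})

test_that("class hues sample only from the class's two bands", {
  bs <- border_set(planted7)
  cb <- bands_from_borders(bs)
  set.seed(51)
  for (k in c(0L, 3L, 6L)) {
    h <- sample_category_hue(cb, k, 400)
    cl <- cb$classes[[k + 1]]
    inl <- h >= wrap_hue(cl$left[1]) & h < wrap_hue(cl$left[2])
    lo_r <- wrap_hue(cl$right[1]); hi_r <- wrap_hue(cl$right[2])
    inr <- if (lo_r <= hi_r) h >= lo_r & h < hi_r else h >= lo_r | h < hi_r
    expect_true(all(inl | inr))
    expect_gt(mean(inl), 0.3) # both bands actually used
  }
})

test_that("the analytic fitness oracle peaks at the planted truth and degrades away", {
  oracle <- planted_fitness_oracle(planted7)
  expect_equal(oracle(border_set(planted7)), 1)
  # moving one border well off its planted position lowers fitness
  offsets <- c(0.02, 0.04, 0.06)
  fits <- vapply(offsets, function(d) {
    p <- planted7; p[4] <- p[4] + d
    as.numeric(oracle(border_set(p)))
  }, numeric(1))
  expect_true(all(diff(c(1, fits)) <= 1e-12))
  expect_lt(fits[3], 1)
  # crowding all classes into one planted category is heavily penalized
  cramped <- border_set(0.22 + (0:6) * 0.02)
  expect_lt(as.numeric(oracle(cramped)), 0.5)
  # degenerate sets are flagged, not crashed
  f0 <- oracle(border_set(c(0.1, 0.105, 0.3, 0.45, 0.6, 0.75, 0.9)))
  expect_equal(as.numeric(f0), 0)
  expect_true(isTRUE(attr(f0, "degenerate")))
})

test_that("trained-head fitness ranks border sets concordantly with the oracle", {
  # concordance requires a categorical representation: on raw color
  # features every disjoint band set is equally learnable, so the check
  # runs on a scratch backbone trained to the planted categories
  oracle <- planted_fitness_oracle(planted7)
  ex <- make_scratch_category_backbone(planted7, n_train = 1500, n_val = 400,
                                       epochs = 60, acc_criterion = 0.8,
                                       seed = 48)
  set.seed(52)
  sets <- c(list(border_set(planted7)),
            lapply(1:7, function(i) random_border_set()))
  f_orc <- vapply(sets, function(b) as.numeric(oracle(b)), numeric(1))
  f_head <- vapply(seq_along(sets), function(i)
    with_seed(100 + i,
              evaluate_fitness(sets[[i]], ex, evolution_config(),
                               n_train_per_class = 60, n_val_per_class = 15)),
    numeric(1))
  expect_gt(cor(f_orc, f_head, method = "spearman"), 0.7)
})

test_that("parent selection respects the tier probabilities and excludes the bottom", {
  cfg <- evolution_config()
  set.seed(53)
  draws <- replicate(20000, select_parent(100, cfg))
  expect_equal(max(draws), 75) # bottom quartile never reproduces
  freq <- c(mean(draws <= 25), mean(draws > 25 & draws <= 50),
            mean(draws > 50 & draws <= 75))
  se <- sqrt(cfg$tier_fracs * (1 - cfg$tier_fracs) / 20000)
  expect_true(all(abs(freq - cfg$tier_fracs) < 3.5 * se))
  # uniform within tier
  top <- draws[draws <= 25]
  expect_gt(suppressWarnings(chisq.test(table(factor(top, levels = 1:25)))$p.value),
            1e-4)
})

test_that("recombination merges close borders and matches the matching oracle", {
  cfg <- evolution_config()
  p <- border_set(planted7)
  set.seed(54)
  child <- recombine_parents(p, p, cfg)
  expect_equal(child$positions, p$positions, tolerance = 1e-12)
  # parents far apart: no merges, child is a 7-subset of the 14 pool
  a <- border_set((0:6) / 7)
  b <- border_set((0:6) / 7 + 0.07)
  pool <- huecat:::merge_parent_borders(a$positions, b$positions, 0.05)
  expect_length(pool, 14)
  child2 <- recombine_parents(a, b, cfg)
  expect_true(all(vapply(child2$positions, function(x)
    any(abs(x - pool) < 1e-9), logical(1))))
  # randomized parents against the closest-first matching oracle
  for (i in 1:30) {
    pa <- sort(runif(7)); pb <- sort(runif(7))
    got <- sort(huecat:::merge_parent_borders(pa, pb, 0.05))
    expect_equal(got, oracle_merge(pa, pb, 0.05), tolerance = 1e-12)
  }
})

test_that("mutation hits the configured rate and spread and respects the switch", {
  cfg <- evolution_config()
  bs <- border_set(planted7)
  expect_identical(mutate_borders(bs, cfg, enabled = FALSE), bs)
  set.seed(55)
  n_slots <- 0; n_hit <- 0; shifts <- numeric(0)
  for (i in 1:6000) {
    m <- mutate_borders(bs, cfg, enabled = TRUE)
    d <- circular_distance(m$positions, bs$positions)
    moved <- vapply(m$positions, function(x)
      min(circular_distance(x, bs$positions)) > 1e-12, logical(1))
    n_slots <- n_slots + 7; n_hit <- n_hit + sum(moved)
    if (any(moved)) {
      shifts <- c(shifts, vapply(m$positions[moved], function(x)
        min(circular_distance(x, bs$positions)), numeric(1)))
    }
  }
  rate_se <- sqrt(0.025 * 0.975 / n_slots)
  expect_lt(abs(n_hit / n_slots - 0.025), 3.5 * rate_se)
  # |N(0, 0.025)| folded mean = 0.025 * sqrt(2/pi)
  expect_lt(abs(mean(shifts) - 0.025 * sqrt(2 / pi)),
            4 * sd(shifts) / sqrt(length(shifts)))
})

test_that("one generation step keeps the population structure and elites", {
  cfg <- evolution_config()
  set.seed(56)
  pop <- replicate(100, random_border_set(), simplify = FALSE)
  fit <- runif(100)
  nxt <- step_generation(pop, fit, cfg, mutation_on = TRUE)
  expect_length(nxt$population, 100)
  ord <- order(-fit)
  for (i in 1:10) {
    expect_identical(nxt$population[[i]], pop[[ord[i]]]) # byte-identical elites
  }
  expect_equal(nxt$elite_fitness, fit[ord[1:10]])
  expect_error(step_generation(pop[1:50], fit[1:50], cfg), "pop_size")
  # genome invariant: 7 strictly distinct circular positions everywhere
  expect_true(all(vapply(nxt$population, function(b)
    length(unique(b$positions)) == 7, logical(1))))
})

test_that("evolution under the oracle is reproducible and monotone", {
  oracle <- planted_fitness_oracle(planted7)
  cfg <- evolution_config(pop_size = 40, n_elite = 4, n_offspring = 36,
                          n_generations = 8, mutation_off_after = 6)
  r1 <- run_evolution(oracle, cfg, seed = 57)
  r2 <- run_evolution(oracle, cfg, seed = 57)
  expect_identical(r1$records, r2$records)
  expect_true(all(diff(r1$best_per_generation) >= -1e-12))
  expect_equal(nrow(r1$records), 40 * 8)
})

test_that("replicate summaries pool solutions and match the circular-median oracle", {
  set.seed(58)
  mats <- lapply(1:12, function(i)
    matrix(wrap_hue(rep(planted7, each = 10) + rnorm(70, 0, 0.01)),
           nrow = 10, byrow = FALSE))
  s <- summarize_replicates(mats)
  expect_equal(unique(s$n_solutions), 120) # 12 runs x top 10
  for (j in 1:7) {
    pooled <- do.call(rbind, mats)[, j]
    expect_lt(circular_distance(s$median[j], oracle_circular_median(pooled)),
              2e-4)
  }
  ident <- lapply(1:3, function(i) matrix(rep(planted7, each = 4), nrow = 4))
  s0 <- summarize_replicates(ident, n_top = 4)
  expect_equal(s0$sd, rep(0, 7))
  expect_equal(s0$median, planted7)
})
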