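test_that("a probe head separates band classes on the analytic extractor", {
  ex <- mean_glyph_rgb_extractor()
  bands <- make_uniform_bands(4, 0)
  head <- train_probe_head(ex, bands,
                           probe_train_config(60, 20, seed = 41))
  expect_equal(head$K, 4L)
  expect_gte(head$best_val, 0.95)
  # separability oracle: a nearest-centroid rule on the band-center
  # colors already classifies fresh samples perfectly
  set.seed(42)
  hues <- unlist(lapply(0:3, function(k) sample_class_hue(bands, k, 25)))
  y <- rep(0:3, each = 25)
  X <- hue_to_rgb(hues)
  centroids <- hue_to_rgb(bands$centers)
  pred <- apply(X, 1, function(x)
    which.min(colSums((t(centroids) - x)^2)) - 1L)
  expect_equal(mean(pred == y), 1)
})

test_that("probe training is deterministic given a seed", {
  ex <- mean_glyph_rgb_extractor()
  bands <- make_uniform_bands(5, 0.2)
  cfg <- probe_train_config(40, 10, seed = 7)
  h1 <- train_probe_head(ex, bands, cfg)
  h2 <- train_probe_head(ex, bands, cfg)
  expect_identical(h1$val_trace, h2$val_trace)
  expect_identical(h1$W, h2$W)
})

test_that("spectrum evaluation produces the full sample grid and a checkable mode row", {
  ex <- mean_glyph_rgb_extractor()
  bands <- make_uniform_bands(4, 0)
  head <- train_probe_head(ex, bands, probe_train_config(60, 20, seed = 43))
  grid <- eval_grid(100, 60)
  row <- with_seed(44, evaluate_spectrum(head, ex, grid))
  expect_equal(dim(row$samples), c(60, 100))
  expect_equal(length(row$samples), 6000) # 100 bins x 60 samples
  recount <- apply(row$samples, 2, function(col) {
    tab <- table(col)
    min(as.integer(names(tab)[tab == max(tab)]))
  })
  expect_equal(row$mode_row, as.integer(recount))
  expect_error(evaluate_spectrum(structure(list(trained = FALSE),
                                           class = "probe_head"), ex, grid),
               "trained")
})

test_that("the invariant-experiment design enumerates shifts by class count", {
  d <- invariant_design(4:9, 150)
  expect_equal(nrow(d), 900)
  expect_equal(nrow(invariant_design(7, 10)), 10)
  expect_equal(d$shift[d$shift_index == 1], rep(0, 6))
  expect_equal(max(d$shift), 149 / 150)
})

test_that("responder rows have the stated transition geometry", {
  grid <- eval_grid(100, 10)
  centers <- bin_centers(100)
  # continuous, eps = 0: each bin takes the class of its nearest band
  # center, so transitions sit at the midpoints between adjacent centers
  bands <- make_uniform_bands(7, 0.03)
  rc <- simulate_row(continuous_responder(0), bands, grid)
  nearest <- vapply(centers, function(h) {
    d <- circular_distance(h, bands$centers)
    which(d == min(d))[1] - 1L
  }, integer(1))
  expect_equal(rc$mode_row, nearest)
  expect_gt(length(find_transitions(rc$mode_row)), 0)
  # categorical, eps = 0: the transition set equals the planted category
  # map's transitions and is invariant to the band shift
  planted <- (0:6) / 7 + 0.02
  expected <- oracle_transitions(planted_category(centers, planted))
  for (s in c(0, 0.04, 0.09)) {
    rk <- simulate_row(categorical_responder(planted),
                       make_uniform_bands(7, s), grid)
    expect_equal(find_transitions(rk$mode_row), expected)
  }
})

test_that("label noise at 60 samples per bin leaves the mode row intact", {
  grid <- eval_grid(100, 60)
  bands <- make_uniform_bands(7, 0.05)
  base <- simulate_row(categorical_responder(planted7, 0), bands, grid)
  noisy <- simulate_row(categorical_responder(planted7, 0.2), bands, grid,
                        seed = 45)
  # binomial tail: a bin's mode flips only if noise overturns a 60-0
  # majority split across 6 other classes; per-bin flip odds are < 1e-3
  expect_gte(mean(noisy$mode_row == base$mode_row), 0.99)
})

test_that("relabeling classes permutes rows and leaves borders unchanged", {
  grid <- eval_grid(100, 8)
  bands <- make_uniform_bands(6, 0.02)
  r <- simulate_row(categorical_responder(planted7), bands, grid, seed = 46)
  perm <- sample(0:5)
  permuted <- perm[r$mode_row + 1L]
  expect_equal(sort(find_transitions(permuted)),
               sort(find_transitions(r$mode_row)))
})

test_that("continuous rows track band shifts bin for bin", {
  grid <- eval_grid(100, 5)
  r0 <- simulate_row(continuous_responder(0), make_uniform_bands(5, 0.001), grid)
  for (d in c(3, 11)) {
    rd <- simulate_row(continuous_responder(0),
                       make_uniform_bands(5, 0.001 + d / 100), grid)
    expect_equal(sort((find_transitions(r0$mode_row) + d) %% 100),
                 sort(find_transitions(rd$mode_row)))
  }
})

test_that("responder stacks mirror the experiment design", {
  rows <- simulate_row_stack(categorical_responder(planted7, 0.05),
                             class_counts = 7, n_shifts = 10,
                             grid = eval_grid(100, 5), seed = 47)
  expect_length(rows, 10)
  expect_equal(nrow(attr(rows, "design")), 10)
  expect_true(all(vapply(rows, function(r) r$K == 7, logical(1))))
})

test_that("the scratch backbone meets its contract on a fast configuration", {
  planted <- planted7
  ex <- make_scratch_category_backbone(planted, n_train = 1500, n_val = 400,
                                       epochs = 60, acc_criterion = 0.8,
                                       seed = 48)
  expect_s3_class(ex, "feature_extractor")
  expect_equal(ex$dim, 7L)
  # extractor dimension equals the configured penultimate width
  ex2 <- make_scratch_category_backbone(planted, hidden = c(16, 5),
                                        n_train = 1500, n_val = 400,
                                        epochs = 60, acc_criterion = 0.5,
                                        seed = 48)
  expect_equal(ex2$dim, 5L)
  # determinism per seed
  exb <- make_scratch_category_backbone(planted, n_train = 1500, n_val = 400,
                                        epochs = 60, acc_criterion = 0.8,
                                        seed = 48)
  expect_identical(ex$meta$val_trace, exb$meta$val_trace)
  # fast word path agrees exactly with render-then-extract
  cfg <- word_stimulus_config()
  f1 <- with_seed(49, ex$word_batch(c(0.25, 0.7), cfg))
  f2 <- with_seed(49, rbind(extract_features(ex, render_word_stimulus(0.25, cfg)),
                            extract_features(ex, render_word_stimulus(0.7, cfg))))
  expect_equal(f1, f2, tolerance = 1e-10, ignore_attr = TRUE)
})
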