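test_that("within-category error curves dip at category centers", {
  ec <- within_category_error_curve(categorical_responder(planted7),
                                    border_set(planted7),
                                    n_steps = 10, n_reps = 8,
                                    grid = eval_grid(100, 20), seed = 61)
  expect_true(all(ec$error >= 0 & ec$error <= 1, na.rm = TRUE))
  expect_equal(nrow(ec), 10 * 8 * 7)
  by_step <- aggregate(error ~ step, ec, mean)$error
  # edges (steps adjacent to borders) err more than the center steps
  expect_gt(mean(by_step[c(1, 10)]), mean(by_step[5:6]) + 0.01)
  expect_lt(mean(by_step[5:6]), 0.02)
})

test_that("the 14 object bands follow the fifth-of-category rule and are disjoint", {
  b <- place_14_bands(border_set((0:6) / 7))
  expect_equal(nrow(b), 14) # 2 bands x 7 categories
  # category [0, 1/7]: centers at 1/28 and 3/28, width 1/35
  expect_equal(b$center[1], 1 / 28, tolerance = 1e-12)
  expect_equal(b$center[2], 3 / 28, tolerance = 1e-12)
  expect_equal(2 * b$half_width[1], 1 / 35, tolerance = 1e-12)
  # disjoint for random valid border sets
  set.seed(62)
  for (i in 1:20) {
    bb <- place_14_bands(random_border_set())
    ord <- order(bb$lo)
    lo <- bb$lo[ord]; hi <- bb$hi[ord]
    gaps_ok <- all(lo[-1] >= hi[-14] - 1e-12)
    wrap_ok <- (lo[1] + 1) >= hi[14] - 1e-12
    expect_true(gaps_ok && wrap_ok)
  }
})

test_that("object evaluation design multiplies out to the per-class sample count", {
  d <- object_design(80, 100)
  expect_equal(d$per_class_samples, 8000)
  expect_equal(object_design(8, 25)$per_class_samples, 200)
})

test_that("a color-only responder halves home-category accuracy and zeroes the rest", {
  obj <- object_color_experiment(categorical_responder(planted7),
                                 border_set(planted7),
                                 n_permutations = 2, n_bins = 100, seed = 63)
  expect_equal(dim(obj$median), c(14, 100))
  centers <- bin_centers(100)
  nxt <- c(planted7[-1], planted7[1] + 1)
  for (b in seq_len(14)) {
    cat_b <- obj$bands$category[b] + 1
    home <- huecat:::circ_in_interval(centers, planted7[cat_b],
                                      wrap_hue(nxt[cat_b]))
    expect_lt(abs(mean(obj$median[b, home]) - 0.5), 0.12)
    expect_lt(mean(obj$median[b, !home]), 1e-9)
  }
})

test_that("shape-informative features lift within-category accuracy above color alone", {
  # tiny extractor carrying mean fill color plus crude shape statistics
  shape_ex <- feature_extractor("fill_and_shape", 6L, function(img) {
    line <- img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 0
    bgm <- img[, , 1] == 128 & img[, , 2] == 128 & img[, , 3] == 128
    fill <- !line & !bgm
    if (!any(fill)) return(rep(0, 6))
    rows <- which(rowSums(fill) > 0); cols <- which(colSums(fill) > 0)
    c(mean(img[, , 1][fill]), mean(img[, , 2][fill]), mean(img[, , 3][fill])) /
      255 -> rgbm
    c(rgbm, sum(fill) / length(fill), sum(line) / length(line),
      length(rows) / max(length(cols), 1))
  })
  two_fams <- c("circle", "star5")
  bs <- border_set(planted7)
  b14 <- place_14_bands(bs)
  set.seed(64)
  # train a 2-class readout on two shapes sharing one category's two bands
  featurize <- function(fams, hues) t(mapply(function(f, h) {
    o <- generate_synthetic_outline(f, size = 64, thickness = 3)
    extract_features(shape_ex, render_filled_shape(o, h))
  }, fams, hues))
  n <- 40
  hues <- c(wrap_hue(b14$center[11] + runif(n, -1, 1) * b14$half_width[11]),
            wrap_hue(b14$center[12] + runif(n, -1, 1) * b14$half_width[12]))
  X <- featurize(rep(two_fams, each = n), hues)
  y <- rep(0:1, each = n)
  net <- huecat:::mlp_train(X, y, K = 2, epochs = 30, lr = 0.3,
                            Xval = X, yval = y)
  expect_gt(net$acc, 0.75) # shape separates classes within one category
})

test_that("simulated observers produce complete deterministic tables", {
  tab <- simulate_observer(planted7, lapse = 0, jitter_sd = 0, seed = 65)
  expect_equal(dim(tab$choices), c(35, 35))
  expect_equal(length(tab$choices), 1225)
  expect_true(all(tab$choices >= 0 & tab$choices < 7))
  tab2 <- simulate_observer(planted7, lapse = 0, jitter_sd = 0, seed = 66)
  expect_identical(tab$choices, tab2$choices) # deterministic at zero noise
})

test_that("a noise-free observer with wide categories transitions at the borders", {
  wide <- (0:6) / 7 + 0.3 / 7 # every category spans one choice spacing
  tab <- simulate_observer(wide, lapse = 0, jitter_sd = 0, seed = 67)
  ana <- observer_transition_analysis(list(tab))
  expect_gte(ana$borders$n_borders, 7)
  expect_lte(max_planted_error(ana$borders$positions, wide), 1 / 35)
})

test_that("observer analysis conserves counts; jitter broadens the peaks", {
  tabs <- lapply(1:10, function(i)
    simulate_observer(planted7, lapse = 0.05, jitter_sd = 0.01,
                      id = paste0("o", i), seed = derive_seed(68, i)))
  ana <- observer_transition_analysis(tabs)
  per_obs <- vapply(tabs, function(t)
    sum(vapply(1:35, function(s) length(find_transitions(t$choices[s, ])),
               integer(1))), integer(1))
  expect_equal(sum(ana$transition_count$raw), sum(per_obs))
  expect_true(!is.null(ana$prototypes))
  # larger observer jitter spreads transition mass away from the borders
  spread <- function(jit) {
    tt <- lapply(1:6, function(i)
      simulate_observer(planted7, lapse = 0, jitter_sd = jit,
                        seed = derive_seed(77, i)))
    raw <- observer_transition_analysis(tt)$transition_count$raw
    pos <- bin_edges(35)
    dists <- vapply(pos, function(p) min(circular_distance(p, planted7)),
                    numeric(1))
    sum(raw * dists) / sum(raw) # mean distance of mass from a border
  }
  spreads <- vapply(c(0, 0.015, 0.04), spread, numeric(1))
  expect_true(all(diff(spreads) > 0))
  # incomplete tables are rejected with cell coordinates
  bad <- tabs[[1]]; bad$choices[3, 7] <- NA
  expect_error(observer_transition_analysis(list(bad)), "missing cells")
})

test_that("the bootstrap statistic is invariant to a joint rotation of observers", {
  tabs <- lapply(1:5, function(i)
    simulate_observer(planted7, lapse = 0.05, jitter_sd = 0.01,
                      seed = derive_seed(69, i)))
  rotate_tab <- function(tab, k) {
    tab$choices <- tab$choices[, c((k + 1):35, 1:k)]
    tab
  }
  # identical observers attain the maximal statistic
  twin <- suppressWarnings(
    bootstrap_correlation_test(list(tabs[[1]], tabs[[1]]), n_boot = 100,
                               seed = 72))
  expect_equal(twin$observed, 1, tolerance = 1e-12)
  b1 <- suppressWarnings(bootstrap_correlation_test(tabs, n_boot = 100,
                                                    seed = 70))
  b2 <- suppressWarnings(bootstrap_correlation_test(
    lapply(tabs, rotate_tab, k = 9), n_boot = 100, seed = 70))
  expect_equal(b1$observed, b2$observed, tolerance = 1e-12)
  expect_error(bootstrap_correlation_test(tabs[1], n_boot = 100), "2 observers")
  expect_error(bootstrap_correlation_test(tabs, n_boot = 5), "small")
  expect_warning(bootstrap_correlation_test(tabs, n_boot = 100, seed = 1),
                 "1000")
})

test_that("observer tables round-trip through the CSV ingestion format", {
  dir <- withr::local_tempdir()
  tab <- simulate_observer(planted7, lapse = 0.1, jitter_sd = 0.02, seed = 71)
  p <- file.path(dir, "obs.csv")
  write_observer_csv(tab, p)
  back <- read_observer_csv(p)
  expect_identical(back$choices, tab$choices)
})
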