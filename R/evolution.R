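# Evolutionary search for the border set that maximizes learning speed
# of a probe head: elitism, tiered biased parent selection,
# closest-first border merging, subset recombination and Gaussian
# circular mutation, with an analytic planted-category fitness oracle
# for desk-scale testing.

#' Construct a border set
#'
#' @param positions circular hue positions (wrapped, sorted ascending
#'   from hue 0); must be pairwise distinct.
#' @return a `border_set`.
#' @export
border_set <- function(positions) {
  pos <- sort(wrap_hue(positions))
  if (length(pos) < 2L) stop("need at least 2 borders", call. = FALSE)
  if (any(diff(c(pos, pos[1] + 1)) <= 0)) {
    stop("border positions must be pairwise distinct", call. = FALSE)
  }
  structure(list(positions = pos, n_borders = length(pos)),
            class = "border_set")
}

#' @export
print.border_set <- function(x, ...) {
  cat(sprintf("<border_set> %s\n",
              paste(sprintf("%.4f", x$positions), collapse = ", ")))
  invisible(x)
}

#' Random border set
#'
#' Positions are i.i.d. uniform, redrawn until all pairwise circular
#' distances exceed `min_gap`.
#'
#' @param n_borders number of borders (default 7).
#' @param min_gap minimum pairwise circular distance (default 0.02).
#' @return a `border_set`.
#' @export
random_border_set <- function(n_borders = 7L, min_gap = 0.02) {
  repeat {
    pos <- sort(stats::runif(n_borders))
    gaps <- diff(c(pos, pos[1] + 1))
    if (all(gaps > min_gap)) return(border_set(pos))
  }
}

#' Evolutionary search configuration
#'
#' Defaults implement the published scheme: population 100, 10 elites +
#' 90 offspring, parents drawn 55%/30%/15% from the three top quartiles
#' (bottom quartile excluded), borders closer than 5% merged during
#' recombination, 2.5% of borders mutated with SD 2.5% of the circle,
#' 40 generations with mutation switched off after 30, 3-epoch fitness
#' training, 12 replicate runs.
#'
#' @param pop_size,n_elite,n_offspring population structure.
#' @param tier_fracs parent-tier probabilities over ranked quartiles.
#' @param merge_threshold circular distance below which parental borders
#'   merge.
#' @param mutation_rate,mutation_sd per-border mutation probability and
#'   shift SD.
#' @param n_generations,mutation_off_after schedule.
#' @param fitness_epochs probe-training epochs in the learning-speed
#'   fitness.
#' @param n_replicates independent runs pooled in the replicate summary.
#' @param n_borders genome size.
#' @param min_span smallest allowed category span before a border set is
#'   flagged degenerate.
#' @return an `evolution_config`.
#' @export
evolution_config <- function(pop_size = 100L, n_elite = 10L,
                             n_offspring = 90L,
                             tier_fracs = c(0.55, 0.30, 0.15),
                             merge_threshold = 0.05, mutation_rate = 0.025,
                             mutation_sd = 0.025, n_generations = 40L,
                             mutation_off_after = 30L, fitness_epochs = 3L,
                             n_replicates = 12L, n_borders = 7L,
                             min_span = 0.02) {
  if (n_elite + n_offspring != pop_size) {
    stop("n_elite + n_offspring must equal pop_size", call. = FALSE)
  }
  if (abs(sum(tier_fracs) - 1) > 1e-12) {
    stop("tier fractions must sum to 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "evolution_config")
}

#' Training bands derived from a border set
#'
#' Each category (the span between adjacent borders) contributes two
#' bands just inside its borders: a gap of 5% of the category span
#' separates each border from its band, and each band is 10% of the span
#' wide. Training hues are drawn uniformly from the union of a class's
#' two bands.
#'
#' @param bs a `border_set`.
#' @param gap_frac,band_frac gap and band width as fractions of the
#'   category span (defaults 0.05 and 0.10).
#' @param min_span smallest span before the set is rejected as
#'   degenerate (default 0.02).
#' @return a `category_bands` object: per class, `left` and `right`
#'   bands as `c(lo, hi)` intervals (hi may wrap past 1) plus the span.
#' @export
bands_from_borders <- function(bs, gap_frac = 0.05, band_frac = 0.10,
                               min_span = 0.02) {
  pos <- bs$positions
  k <- length(pos)
  nxt <- c(pos[-1], pos[1] + 1)
  spans <- nxt - pos
  if (any(spans < min_span)) {
    stop("degenerate-category: span below ", min_span, call. = FALSE)
  }
  classes <- lapply(seq_len(k), function(i) {
    s <- spans[i]
    list(left = pos[i] + c(gap_frac, gap_frac + band_frac) * s,
         right = nxt[i] - c(gap_frac + band_frac, gap_frac) * s,
         span = s)
  })
  structure(list(borders = pos, classes = classes, n_classes = k),
            class = "category_bands")
}

#' Sample training hues for one class of a category-band set
#' @param cb a `category_bands`.
#' @param class_index 0-based class.
#' @param n number of draws.
#' @return hues from the union of the class's two bands.
#' @export
sample_category_hue <- function(cb, class_index, n = 1L) {
  cl <- cb$classes[[class_index + 1L]]
  use_left <- stats::runif(n) < 0.5 # both bands have equal width
  lo <- ifelse(use_left, cl$left[1], cl$right[1])
  hi <- ifelse(use_left, cl$left[2], cl$right[2])
  wrap_hue(lo + stats::runif(n) * (hi - lo))
}

# split a circular interval [lo, hi) (hi may exceed 1) into linear
# segments inside [0, 1)
split_interval <- function(lo, hi) {
  len <- hi - lo
  if (len <= 0) return(matrix(numeric(0), ncol = 2))
  lo <- wrap_hue(lo)
  if (lo + len <= 1) matrix(c(lo, lo + len), ncol = 2)
  else rbind(c(lo, 1), c(0, lo + len - 1))
}

seg_overlap <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + max(0, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
  }
  tot
}

#' Analytic learning-speed fitness oracle for planted categories
#'
#' Desk-scale stand-in for the trained-head fitness: the achievable
#' accuracy of an ideal categorical observer. Each planted category is
#' assigned to the candidate class holding the largest share of its
#' band mass; fitness is the mean assigned mass over classes. It equals
#' 1 exactly when every class's bands fall in one planted category owned
#' by no other class, and degrades as borders move off the planted
#' positions or classes crowd into shared categories.
#'
#' @param planted planted `border_set` or sorted positions.
#' @return a function `border_set -> fitness in [0, 1]` (degenerate sets
#'   score 0 with attribute `degenerate`).
#' @export
planted_fitness_oracle <- function(planted) {
  if (inherits(planted, "border_set")) planted <- planted$positions
  planted <- sort(wrap_hue(planted))
  nxt <- c(planted[-1], planted[1] + 1)
  cat_segs <- lapply(seq_along(planted), function(j)
    split_interval(planted[j], nxt[j]))
  function(bs) {
    cb <- tryCatch(bands_from_borders(bs),
                   error = function(e) NULL)
    if (is.null(cb)) return(structure(0, degenerate = TRUE))
    K <- cb$n_classes
    m <- matrix(0, K, length(planted)) # band-mass share of class k in category c
    for (k in seq_len(K)) {
      cl <- cb$classes[[k]]
      segs <- rbind(split_interval(cl$left[1], cl$left[2]),
                    split_interval(cl$right[1], cl$right[2]))
      mass <- sum(segs[, 2] - segs[, 1])
      for (c in seq_along(cat_segs)) {
        m[k, c] <- seg_overlap(segs, cat_segs[[c]]) / mass
      }
    }
    sum(apply(m, 2, max)) / K
  }
}

#' Learning-speed fitness of a border set under a feature extractor
#'
#' A probe head is trained for `fitness_epochs` epochs on word stimuli
#' whose hues come from [bands_from_borders()]; the best validation
#' accuracy is the fitness. Degenerate border sets score 0 (flagged).
#'
#' @param bs a `border_set`.
#' @param ex a `feature_extractor`.
#' @param cfg an [evolution_config()].
#' @param n_train_per_class,n_val_per_class sample sizes (defaults 100
#'   and 20, the desk preset).
#' @param stim_cfg a [word_stimulus_config()].
#' @return fitness in `[0, 1]`.
#' @export
evaluate_fitness <- function(bs, ex, cfg = evolution_config(),
                             n_train_per_class = 100L, n_val_per_class = 20L,
                             stim_cfg = word_stimulus_config()) {
  cb <- tryCatch(bands_from_borders(bs, min_span = cfg$min_span),
                 error = function(e) NULL)
  if (is.null(cb)) return(structure(0, degenerate = TRUE))
  K <- cb$n_classes
  pcfg <- probe_train_config(n_train_per_class, n_val_per_class,
                             epochs = cfg$fitness_epochs)
  y_tr <- rep(0:(K - 1), each = n_train_per_class)
  y_va <- rep(0:(K - 1), each = n_val_per_class)
  h_tr <- unlist(lapply(0:(K - 1), function(k)
    sample_category_hue(cb, k, n_train_per_class)))
  h_va <- unlist(lapply(0:(K - 1), function(k)
    sample_category_hue(cb, k, n_val_per_class)))
  X_tr <- word_features(ex, h_tr, stim_cfg)
  X_va <- word_features(ex, h_va, stim_cfg)
  net <- mlp_train(X_tr, y_tr, K = K, hidden = 0L, epochs = pcfg$epochs,
                   batch_size = pcfg$batch_size, lr = pcfg$lr,
                   momentum = pcfg$momentum, Xval = X_va, yval = y_va)
  net$acc
}

#' Draw one parent rank from a fitness-ranked population
#'
#' Ranks are split into quartile tiers; the three top tiers are drawn
#' with the configured probabilities (55/30/15% at population 100) and
#' uniformly within a tier. The bottom tier never reproduces. Population
#' sizes other than 100 scale the tiers proportionally.
#'
#' @param pop_size ranked population size.
#' @param cfg an [evolution_config()].
#' @return a 1-based rank (1 = fittest).
#' @export
select_parent <- function(pop_size, cfg = evolution_config()) {
  q <- pop_size %/% 4
  tier <- sample.int(3, 1, prob = cfg$tier_fracs)
  lo <- (tier - 1) * q + 1
  hi <- tier * q
  sample(lo:hi, 1)
}

# greedy closest-first disjoint matching of two parents' borders; a
# border involved in more than one candidate pair has its working
# threshold halved (the "threshold is lowered in crowded regions" rule)
merge_parent_borders <- function(a, b, threshold) {
  na <- length(a); nb <- length(b)
  d <- outer(a, b, circular_distance)
  cand <- d < threshold
  row_inv <- rowSums(cand); col_inv <- colSums(cand)
  work <- matrix(threshold, na, nb)
  conflicted <- outer(row_inv > 1, col_inv > 1, "|")
  work[conflicted] <- threshold / 2
  eligible <- which(d < work, arr.ind = TRUE)
  if (nrow(eligible) > 0) {
    eligible <- eligible[order(d[eligible]), , drop = FALSE]
  }
  used_a <- logical(na); used_b <- logical(nb)
  merged <- numeric(0)
  for (r in seq_len(nrow(eligible))) {
    i <- eligible[r, 1]; j <- eligible[r, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    merged <- c(merged, circular_weighted_mean(c(a[i], b[j])))
  }
  c(merged, a[!used_a], b[!used_b])
}

#' Recombine two parent border sets
#'
#' Borders occupying similar positions across the parents (circular
#' distance below the merge threshold) are combined closest-first into
#' their circular mean; from the pooled borders, `n_borders` distinct
#' positions are drawn uniformly without replacement. Exact duplicates in
#' the pool are jittered by 1e-4 before drawing.
#'
#' @param p1,p2 parent `border_set`s.
#' @param cfg an [evolution_config()].
#' @return a child `border_set`.
#' @export
recombine_parents <- function(p1, p2, cfg = evolution_config()) {
  pool <- merge_parent_borders(p1$positions, p2$positions,
                               cfg$merge_threshold)
  while (anyDuplicated(pool)) {
    dup <- duplicated(pool)
    pool[dup] <- wrap_hue(pool[dup] + 1e-4)
  }
  n <- cfg$n_borders
  child <- if (length(pool) == n) pool else pool[sample.int(length(pool), n)]
  border_set(child)
}

#' Mutate a border set
#'
#' Each border is independently selected with probability
#' `mutation_rate`; selected borders are shifted by a wrapped normal
#' draw with SD `mutation_sd` (fractions of the circle). Identity when
#' mutation is disabled.
#'
#' @param bs a `border_set`.
#' @param cfg an [evolution_config()].
#' @param enabled mutation switch (generations past `mutation_off_after`
#'   pass `FALSE`).
#' @return a `border_set`.
#' @export
mutate_borders <- function(bs, cfg = evolution_config(), enabled = TRUE) {
  if (!enabled) return(bs)
  pos <- bs$positions
  hit <- stats::runif(length(pos)) < cfg$mutation_rate
  if (any(hit)) {
    pos[hit] <- wrap_hue(pos[hit] + stats::rnorm(sum(hit), 0, cfg$mutation_sd))
    while (anyDuplicated(pos)) {
      dup <- duplicated(pos)
      pos[dup] <- wrap_hue(pos[dup] + 1e-4)
    }
  }
  border_set(pos)
}

#' Advance one generation
#'
#' The top `n_elite` members are copied unchanged; `n_offspring` children
#' are produced by tiered parent selection, recombination and (optional)
#' mutation. Two distinct parents are drawn for every child.
#'
#' @param pop list of `border_set` of length `pop_size`.
#' @param fitnesses numeric fitness per member.
#' @param cfg an [evolution_config()].
#' @param mutation_on logical.
#' @return list with `population` (the next generation; elites first) and
#'   `elite_fitness` (carried fitness of the copied elites).
#' @export
step_generation <- function(pop, fitnesses, cfg = evolution_config(),
                            mutation_on = TRUE) {
  if (length(pop) != cfg$pop_size || length(fitnesses) != cfg$pop_size) {
    stop("population must have exactly pop_size evaluated members",
         call. = FALSE)
  }
  ord <- order(-fitnesses)
  elites <- pop[ord[seq_len(cfg$n_elite)]]
  offspring <- vector("list", cfg$n_offspring)
  for (i in seq_len(cfg$n_offspring)) {
    r1 <- select_parent(cfg$pop_size, cfg)
    repeat {
      r2 <- select_parent(cfg$pop_size, cfg)
      if (r2 != r1) break
    }
    child <- recombine_parents(pop[[ord[r1]]], pop[[ord[r2]]], cfg)
    offspring[[i]] <- mutate_borders(child, cfg, enabled = mutation_on)
  }
  list(population = c(elites, offspring),
       elite_fitness = fitnesses[ord[seq_len(cfg$n_elite)]])
}

#' Run the evolutionary border search
#'
#' Initializes `pop_size` random border sets, evaluates fitness with a
#' per-member derived seed, and iterates selection, recombination and
#' mutation for `n_generations` generations; mutation is switched off
#' after `mutation_off_after`. Elites carry their fitness forward, so the
#' best recorded fitness never decreases.
#'
#' @param fitness function `border_set -> numeric` (e.g.
#'   [planted_fitness_oracle()] output, or a closure around
#'   [evaluate_fitness()]).
#' @param cfg an [evolution_config()].
#' @param seed integer run seed.
#' @return list with `population` (final, ranked), `fitness` (final,
#'   ranked), `records` (data frame: generation, member, fitness) and
#'   `best_per_generation`.
#' @export
run_evolution <- function(fitness, cfg = evolution_config(), seed = 1L) {
  pop <- with_seed(derive_seed(seed, 0L),
                   replicate(cfg$pop_size,
                             random_border_set(cfg$n_borders, cfg$min_span),
                             simplify = FALSE))
  fit <- rep(NA_real_, cfg$pop_size)
  records <- vector("list", cfg$n_generations)
  best <- numeric(cfg$n_generations)
  for (gen in seq_len(cfg$n_generations)) {
    todo <- which(is.na(fit))
    for (i in todo) {
      fit[i] <- as.numeric(with_seed(derive_seed(seed, gen, i),
                                     fitness(pop[[i]])))
    }
    records[[gen]] <- data.frame(generation = gen,
                                 member = seq_len(cfg$pop_size),
                                 fitness = fit)
    best[gen] <- max(fit)
    if (gen < cfg$n_generations) {
      stepped <- with_seed(
        derive_seed(seed, gen, 0L, 99L),
        step_generation(pop, fit, cfg,
                        mutation_on = gen < cfg$mutation_off_after)
      )
      pop <- stepped$population
      fit <- c(stepped$elite_fitness, rep(NA_real_, cfg$n_offspring))
    }
  }
  ord <- order(-fit)
  list(population = pop[ord], fitness = fit[ord],
       records = do.call(rbind, records), best_per_generation = best)
}

#' Summarize replicate evolutionary runs
#'
#' Pools the top `n_top` solutions of every run (12 runs x top 10 = 120
#' solutions at published scale), orders each solution's borders left to
#' right from hue 0, and reports the circular median and circular SD per
#' ordinal border position.
#'
#' @param runs list of [run_evolution()] results (or matrices of border
#'   positions, one row per solution).
#' @param n_top solutions taken per run (default 10).
#' @return data frame: `ordinal`, `median`, `sd`, `n_solutions`.
#' @export
summarize_replicates <- function(runs, n_top = 10L) {
  mats <- lapply(runs, function(r) {
    if (is.matrix(r)) return(r)
    do.call(rbind, lapply(r$population[seq_len(n_top)],
                          function(b) b$positions))
  })
  nb <- unique(vapply(mats, ncol, integer(1)))
  if (length(nb) != 1L) stop("runs disagree on the number of borders",
                             call. = FALSE)
  pooled <- do.call(rbind, mats)
  med <- vapply(seq_len(nb), function(j) circular_median(pooled[, j]),
                numeric(1))
  sds <- vapply(seq_len(nb), function(j) circular_sd(pooled[, j]), numeric(1))
  data.frame(ordinal = seq_len(nb), median = med, sd = sds,
             n_solutions = nrow(pooled))
}

#' Circular median of hue values
#'
#' The sample value minimizing the summed circular distances to all
#' other values (ties to the first such value in sort order).
#'
#' @param h hue vector.
#' @return a hue in `[0, 1)`.
#' @export
circular_median <- function(h) {
  h <- sort(wrap_hue(h))
  cost <- vapply(h, function(x) sum(circular_distance(x, h)), numeric(1))
  h[which.min(cost)]
}

#' Circular standard deviation of hue values (in circle fractions)
#' @param h hue vector.
#' @return nonnegative dispersion; 0 for identical values.
#' @export
circular_sd <- function(h) {
  ang <- 2 * pi * wrap_hue(h)
  R <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  R <- min(R, 1)
  sqrt(pmax(0, -2 * log(R))) / (2 * pi)
}
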