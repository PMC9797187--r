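# Experiment drivers: the within-category band-shifting experiment on
# multi-word stimuli, the 14-class colored-objects experiment, and the
# match-to-sample psychophysics analysis (transition counts over
# observers, bootstrap correlation test, observer simulator).
#
# Every driver accepts either a feature_extractor (the faithful trained
# path) or a responder_model (the desk-scale simulation path), so all
# results are reproducible end-to-end from seeds with no downloads.

# minimal band-set-like object for responder classification: only
# centers and n_classes are consulted
pseudo_bands <- function(centers) {
  structure(list(n_classes = length(centers), centers = wrap_hue(centers),
                 half_width = NA_real_),
            class = "hueband_set")
}

#' Within-category error curve under shifting training bands
#'
#' For each of `n_steps` band positions (sliding from the left border of
#' every category to its right border) and `n_reps` repetitions, a
#' 7-class readout is trained on multi-word stimuli from bands of width
#' `band_frac` of each category span, then evaluated on the spectrum
#' bins whose centers fall inside the trained bands; the error is the
#' misclassification proportion there.
#'
#' With a `responder_model` engine no readout is trained: the responder
#' classifies the evaluation bins directly, with its planted borders
#' re-jittered per repetition (`responder_jitter_sd`) to emulate the
#' border fuzziness of a trained network.
#'
#' @param engine a `feature_extractor` or a categorical
#'   `responder_model`.
#' @param borders a `border_estimate` or `border_set` with the category
#'   borders (7 at published scale).
#' @param n_steps,n_reps design (defaults 10 and 15).
#' @param band_frac band width as a fraction of the category span
#'   (default 0.10).
#' @param grid an [eval_grid()]; `samples_per_bin` evaluation samples
#'   are classified per in-band bin.
#' @param cfg a [probe_train_config()] (extractor path).
#' @param stim_cfg a [word_stimulus_config()] for multi-word rendering.
#' @param responder_jitter_sd per-repetition border jitter SD (responder
#'   path; default 0.01).
#' @param seed integer seed.
#' @return an `error_curve` data frame: `category` (0-based), `step`,
#'   `rep`, `error`.
#' @export
within_category_error_curve <- function(engine, borders, n_steps = 10L,
                                        n_reps = 15L, band_frac = 0.10,
                                        grid = eval_grid(100L, 20L),
                                        cfg = probe_train_config(),
                                        stim_cfg = word_stimulus_config(),
                                        responder_jitter_sd = 0.01,
                                        seed = 1L) {
  pos <- if (inherits(borders, "border_set")) borders$positions
         else borders$positions
  pos <- sort(wrap_hue(pos))
  K <- length(pos)
  nxt <- c(pos[-1], pos[1] + 1)
  spans <- nxt - pos
  centers <- bin_centers(grid$n_bins)
  is_responder <- inherits(engine, "responder_model")
  out <- vector("list", n_steps * n_reps)
  row_i <- 0L
  for (j in seq_len(n_steps)) {
    frac <- if (n_steps == 1L) 0.5 else (j - 1) / (n_steps - 1)
    lo <- pos + frac * (1 - band_frac) * spans
    hi <- lo + band_frac * spans
    band_centers <- wrap_hue((lo + hi) / 2)
    in_band <- lapply(seq_len(K), function(k)
      which(circ_in_interval(centers, wrap_hue(lo[k]), wrap_hue(hi[k]))))
    for (r in seq_len(n_reps)) {
      row_i <- row_i + 1L
      err <- with_seed(derive_seed(seed, j, r), {
        if (is_responder) {
          model <- engine
          if (model$kind == "categorical" && responder_jitter_sd > 0) {
            model <- categorical_responder(
              wrap_hue(model$borders + stats::rnorm(K, 0, responder_jitter_sd)),
              model$label_noise)
          }
          pb <- pseudo_bands(band_centers)
          vapply(seq_len(K), function(k) {
            bins <- in_band[[k]]
            if (length(bins) == 0L) return(NA_real_)
            hues <- rep(centers[bins], each = grid$samples_per_bin)
            labs <- responder_labels(model, hues, pb)
            eps <- model$label_noise
            if (eps > 0) {
              flip <- stats::runif(length(labs)) < eps
              labs[flip] <- (labs[flip] +
                sample.int(K - 1, sum(flip), replace = TRUE)) %% K
            }
            mean(labs != (k - 1L))
          }, numeric(1))
        } else {
          featurize <- function(hues) {
            t(vapply(hues, function(h)
              extract_features(engine, render_multiword_stimulus(h, stim_cfg)),
              numeric(engine$dim)))
          }
          sample_hue_k <- function(k, n) wrap_hue(lo[k] + stats::runif(n) *
                                                   (hi[k] - lo[k]))
          y_tr <- rep(0:(K - 1), each = cfg$n_train_per_class)
          y_va <- rep(0:(K - 1), each = cfg$n_val_per_class)
          h_tr <- unlist(lapply(seq_len(K), function(k)
            sample_hue_k(k, cfg$n_train_per_class)))
          h_va <- unlist(lapply(seq_len(K), function(k)
            sample_hue_k(k, cfg$n_val_per_class)))
          net <- mlp_train(featurize(h_tr), y_tr, K = K, hidden = 0L,
                           epochs = cfg$epochs, batch_size = cfg$batch_size,
                           lr = cfg$lr, momentum = cfg$momentum,
                           Xval = featurize(h_va), yval = y_va)
          head <- structure(list(W = net$W2, b = net$b2, K = K,
                                 dim = nrow(net$W2), trained = TRUE),
                            class = "probe_head")
          vapply(seq_len(K), function(k) {
            bins <- in_band[[k]]
            if (length(bins) == 0L) return(NA_real_)
            hues <- rep(centers[bins], each = grid$samples_per_bin)
            labs <- predict_probe(head, featurize(hues))
            mean(labs != (k - 1L))
          }, numeric(1))
        }
      })
      out[[row_i]] <- data.frame(category = 0:(K - 1), step = j, rep = r,
                                 error = err)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("error_curve", class(res))
  res
}

#' Place the 14 object-experiment training bands
#'
#' Two bands per category: each takes up 1/5 of the category span and is
#' centered on the midpoint of the category's left and right halves.
#' Bands are pairwise disjoint for any valid border set.
#'
#' @param borders a `border_set` / `border_estimate` with 7 borders.
#' @return data frame: `band` (0-based), `category`, `side`, `center`,
#'   `half_width`, `lo`, `hi`.
#' @export
place_14_bands <- function(borders) {
  pos <- sort(wrap_hue(borders$positions))
  k <- length(pos)
  nxt <- c(pos[-1], pos[1] + 1)
  spans <- nxt - pos
  rows <- lapply(seq_len(k), function(i) {
    s <- spans[i]
    ctr <- pos[i] + c(1, 3) * s / 4
    data.frame(category = i - 1L, side = c("left", "right"),
               center = wrap_hue(ctr), half_width = s / 10,
               lo = wrap_hue(ctr - s / 10), hi = wrap_hue(ctr + s / 10))
  })
  out <- do.call(rbind, rows)
  out$band <- seq_len(nrow(out)) - 1L
  out[, c("band", "category", "side", "center", "half_width", "lo", "hi")]
}

#' Evaluation design of the colored-objects experiment
#' @param n_eval_outlines held-out drawings per class (default 80).
#' @param n_bins spectrum steps (default 100).
#' @return list with `per_class_samples` (8000 at published scale).
#' @export
object_design <- function(n_eval_outlines = 80L, n_bins = 100L) {
  list(n_eval_outlines = n_eval_outlines, n_bins = n_bins,
       per_class_samples = n_eval_outlines * n_bins)
}

#' Colored-objects generalization experiment
#'
#' Per permutation, the 14 shape families are assigned to the 14 bands
#' from [place_14_bands()]; a 14-class readout is trained on
#' enclosure-filled outlines colored from the assigned bands, then each
#' class is evaluated on freshly generated held-out outlines filled at
#' every spectrum hue. Accuracies are aggregated as the median and SD
#' over permutations.
#'
#' With a `responder_model` engine the classification is color-only:
#' each evaluation hue is labeled by the class whose band center shares
#' its planted category (nearest center among the sharers), without any
#' training.
#'
#' @param engine a `feature_extractor` or `responder_model`.
#' @param borders the category borders (7).
#' @param families shape family names (default [shape_families()]).
#' @param n_permutations iterations with re-permuted object assignment
#'   (default 100).
#' @param n_train,n_val training/validation outlines per class
#'   (defaults 500 and 50).
#' @param n_eval_outlines held-out outlines per class (default 80).
#' @param n_bins spectrum steps (default 100).
#' @param size,thickness outline raster geometry.
#' @param cfg a [probe_train_config()] (epochs etc. for the readout).
#' @param seed integer seed.
#' @return an `object_experiment_result`: `median` and `sd` accuracy
#'   matrices (14 x n_bins), the `bands` table and the design.
#' @export
object_color_experiment <- function(engine, borders,
                                    families = shape_families(),
                                    n_permutations = 100L, n_train = 500L,
                                    n_val = 50L, n_eval_outlines = 80L,
                                    n_bins = 100L, size = 224L,
                                    thickness = 4L,
                                    cfg = probe_train_config(), seed = 1L) {
  bands <- place_14_bands(borders)
  nb <- nrow(bands)
  if (length(families) != nb) {
    stop("need exactly ", nb, " shape families", call. = FALSE)
  }
  centers <- bin_centers(n_bins)
  is_responder <- inherits(engine, "responder_model")
  acc <- array(NA_real_, dim = c(n_permutations, nb, n_bins))
  band_hue <- function(b, n) {
    wrap_hue(bands$center[b] + stats::runif(n, -bands$half_width[b],
                                            bands$half_width[b]))
  }
  for (p in seq_len(n_permutations)) {
    acc[p, , ] <- with_seed(derive_seed(seed, p), {
      perm <- sample.int(nb) # class b trains on families[perm[b]]
      if (is_responder) {
        pb <- pseudo_bands(bands$center)
        labs <- responder_labels(engine, centers, pb)
        a <- matrix(0, nb, n_bins)
        for (b in seq_len(nb)) a[b, ] <- as.numeric(labs == (b - 1L))
        a
      } else {
        featurize <- function(fams, hues) {
          t(mapply(function(fam, h) {
            o <- generate_synthetic_outline(fam, size = size,
                                            thickness = thickness)
            extract_features(engine, render_filled_shape(o, h))
          }, fams, hues))
        }
        y_tr <- rep(0:(nb - 1), each = n_train)
        y_va <- rep(0:(nb - 1), each = n_val)
        f_tr <- rep(families[perm], each = n_train)
        f_va <- rep(families[perm], each = n_val)
        h_tr <- unlist(lapply(seq_len(nb), function(b) band_hue(b, n_train)))
        h_va <- unlist(lapply(seq_len(nb), function(b) band_hue(b, n_val)))
        net <- mlp_train(featurize(f_tr, h_tr), y_tr, K = nb, hidden = 0L,
                         epochs = cfg$epochs, batch_size = cfg$batch_size,
                         lr = cfg$lr, momentum = cfg$momentum,
                         Xval = featurize(f_va, h_va), yval = y_va)
        head <- structure(list(W = net$W2, b = net$b2, K = nb,
                               trained = TRUE), class = "probe_head")
        a <- matrix(0, nb, n_bins)
        for (b in seq_len(nb)) {
          fams <- rep(families[perm[b]], n_eval_outlines * n_bins)
          hues <- rep(centers, each = n_eval_outlines)
          labs <- predict_probe(head, featurize(fams, hues))
          a[b, ] <- colMeans(matrix(labs == (b - 1L),
                                    nrow = n_eval_outlines))
        }
        a
      }
    })
  }
  structure(
    list(median = apply(acc, c(2, 3), stats::median),
         sd = apply(acc, c(2, 3), stats::sd),
         accuracy = acc, bands = bands, families = families,
         design = object_design(n_eval_outlines, n_bins)),
    class = "object_experiment_result"
  )
}

## ---- psychophysics ----------------------------------------------------

#' Simulate one match-to-sample observer
#'
#' The observer owns a jittered copy of the planted borders. On each of
#' the `n_targets x n_shifts` trials the 7 choice hues are the shifted
#' equidistant set; the observer picks a choice whose category matches
#' the target's (the first of several equally valid matches, the
#' closest hue when no choice shares the category), lapsing to a
#' uniform choice with probability `lapse`. With `lapse = 0` and
#' `jitter_sd = 0` the table is a deterministic function of the planted
#' borders.
#'
#' @param planted planted `border_set` or sorted positions.
#' @param lapse lapse rate in `[0, 1)`.
#' @param jitter_sd per-border jitter SD for this observer.
#' @param n_targets,n_shifts grid size (defaults 35 x 35, 1225 trials).
#' @param n_choices peripheral choices per trial (default 7).
#' @param id observer identifier.
#' @param seed integer seed.
#' @return an `observer_table` with a complete `n_shifts x n_targets`
#'   0-based choice matrix.
#' @export
simulate_observer <- function(planted, lapse = 0, jitter_sd = 0,
                              n_targets = 35L, n_shifts = 35L,
                              n_choices = 7L, id = "sim", seed = 1L) {
  if (inherits(planted, "border_set")) planted <- planted$positions
  stopifnot(lapse >= 0, lapse < 1)
  with_seed(seed, {
    b <- sort(wrap_hue(planted +
                         stats::rnorm(length(planted), 0, jitter_sd)))
    targets <- bin_centers(n_targets)
    choices <- matrix(NA_integer_, n_shifts, n_targets)
    for (s in seq_len(n_shifts)) {
      choice_hues <- wrap_hue((0:(n_choices - 1)) / n_choices +
                                (s - 1) / n_shifts)
      choice_cat <- planted_category(choice_hues, b)
      for (t in seq_len(n_targets)) {
        if (lapse > 0 && stats::runif(1) < lapse) {
          choices[s, t] <- sample.int(n_choices, 1) - 1L
          next
        }
        tc <- planted_category(targets[t], b)
        cand <- which(choice_cat == tc)
        if (length(cand) == 0L) {
          # no category-matching option: fall back to the closest hue
          d <- circular_distance(targets[t], choice_hues)
          choices[s, t] <- which.min(d) - 1L
        } else {
          # several same-category options are equally valid matches;
          # the pick is the first candidate, so the chosen class is
          # constant within a category (the candidate set only changes
          # at borders) and no sub-category structure leaks into the
          # transition counts
          choices[s, t] <- cand[1] - 1L
        }
      }
    }
    structure(list(choices = choices, id = id, n_targets = n_targets,
                   n_shifts = n_shifts, n_choices = n_choices),
              class = "observer_table")
  })
}

#' @export
print.observer_table <- function(x, ...) {
  cat(sprintf("<observer_table> %s: %d x %d trials, %d choices\n",
              x$id, x$n_shifts, x$n_targets, x$n_choices))
  invisible(x)
}

check_observer_table <- function(tab) {
  if (!inherits(tab, "observer_table")) stop("not an observer_table",
                                             call. = FALSE)
  miss <- which(is.na(tab$choices), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop(sprintf("observer %s: missing cells at (shift, target) %s", tab$id,
                 paste(sprintf("(%d, %d)", miss[, 1], miss[, 2]),
                       collapse = ", ")),
         call. = FALSE)
  }
  invisible(tab)
}

# per-bin transition counts for one observer (summed over choice-set rows)
observer_transition_counts <- function(tab) {
  counts <- integer(tab$n_targets)
  for (s in seq_len(tab$n_shifts)) {
    tr <- find_transitions(tab$choices[s, ])
    counts[tr + 1L] <- counts[tr + 1L] + 1L
  }
  counts
}

#' Transition-count analysis over observers
#'
#' Per observer and choice-set row, the chosen-class sequence over the
#' target hues is reduced to circular transitions; counts are cumulated
#' over rows and observers, then peaks and reciprocal-weighted
#' prototypes are computed exactly as in the network analysis (same
#' implementation, 35-bin resolution).
#'
#' @param tables list of complete `observer_table`s.
#' @param sigma smoothing SD in bins (default 1.5).
#' @param min_separation,prominence_frac peak-detection settings
#'   (defaults 2 bins and 0.1, scaled to the 35-bin grid).
#' @return list with `transition_count`, `borders` and `prototypes`.
#' @export
observer_transition_analysis <- function(tables, sigma = 1.5,
                                         min_separation = 2,
                                         prominence_frac = 0.1) {
  if (length(tables) < 1L) stop("need at least one table", call. = FALSE)
  lapply(tables, check_observer_table)
  n <- unique(vapply(tables, function(t) t$n_targets, integer(1)))
  if (length(n) != 1L) stop("tables disagree on target grid", call. = FALSE)
  raw <- Reduce(`+`, lapply(tables, observer_transition_counts))
  tc <- structure(
    list(n_bins = n, raw = as.integer(raw),
         smoothed = circ_gauss_smooth(raw, sigma), sigma = sigma,
         n_rows = sum(vapply(tables, function(t) t$n_shifts, integer(1)))),
    class = "transition_count"
  )
  borders <- detect_peaks(tc, min_separation = min_separation,
                          prominence_frac = prominence_frac)
  protos <- if (borders$n_borders >= 2L) compute_prototypes(borders, tc)
            else NULL
  list(transition_count = tc, borders = borders, prototypes = protos)
}

#' Bootstrap test of transition-count alignment across observers
#'
#' The statistic is the mean pairwise Pearson correlation between
#' observers' per-bin transition counts. The null distribution is built
#' by independently circularly shifting every observer's count vector by
#' a uniform random offset in each replicate; the p-value is the
#' fraction of null statistics at least as large as the observed one.
#'
#' @param tables list of >= 2 complete `observer_table`s.
#' @param n_boot bootstrap replicates (default 10000; below 1000 warns,
#'   below 10 errors).
#' @param seed integer seed.
#' @return list with `p_value`, `observed`, `null` (the replicate
#'   statistics).
#' @export
bootstrap_correlation_test <- function(tables, n_boot = 10000L, seed = 1L) {
  if (length(tables) < 2L) stop("need at least 2 observers", call. = FALSE)
  if (n_boot < 10) stop("n_boot is too small", call. = FALSE)
  if (n_boot < 1000) warning("n_boot below 1000; p-value resolution is coarse")
  lapply(tables, check_observer_table)
  counts <- do.call(rbind, lapply(tables, observer_transition_counts))
  if (any(apply(counts, 1, stats::sd) == 0)) {
    stop("an observer has constant transition counts; correlation undefined",
         call. = FALSE)
  }
  n <- ncol(counts); m <- nrow(counts)
  z <- t(scale(t(counts))) / sqrt(n - 1) # rows: unit-variance, zero-mean
  pair_mean <- function(zz) {
    C <- zz %*% t(zz)
    mean(C[upper.tri(C)])
  }
  observed <- pair_mean(z)
  null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      off <- sample.int(n, m, replace = TRUE) - 1L
      zs <- z
      for (i in seq_len(m)) {
        if (off[i] > 0) zs[i, ] <- z[i, c((off[i] + 1):n, 1:off[i])]
      }
      pair_mean(zs)
    }, numeric(1))
  })
  list(p_value = mean(null >= observed), observed = observed, null = null)
}

#' Write / read an observer table as CSV
#'
#' One row per trial with columns `target_hue_index`, `shift_index`,
#' `choice_index` (all 0-based), the ingestion format for external data.
#'
#' @param tab an `observer_table`.
#' @param path CSV file.
#' @export
write_observer_csv <- function(tab, path) {
  check_observer_table(tab)
  idx <- expand.grid(shift_index = seq_len(tab$n_shifts) - 1L,
                     target_hue_index = seq_len(tab$n_targets) - 1L)
  df <- data.frame(target_hue_index = idx$target_hue_index,
                   shift_index = idx$shift_index,
                   choice_index = tab$choices[cbind(idx$shift_index + 1L,
                                                    idx$target_hue_index + 1L)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observer_csv
#' @param id observer id for the loaded table.
#' @param n_choices number of choice alternatives (default 7).
#' @export
read_observer_csv <- function(path, id = basename(path), n_choices = 7L) {
  df <- utils::read.csv(path)
  n_targets <- max(df$target_hue_index) + 1L
  n_shifts <- max(df$shift_index) + 1L
  choices <- matrix(NA_integer_, n_shifts, n_targets)
  choices[cbind(df$shift_index + 1L, df$target_hue_index + 1L)] <-
    df$choice_index
  check_observer_table(
    structure(list(choices = choices, id = id, n_targets = n_targets,
                   n_shifts = n_shifts, n_choices = n_choices),
              class = "observer_table"))
}
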