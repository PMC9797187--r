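# Probe-head (readout) training over a frozen feature extractor,
# spectrum-wide evaluation, the shifting-band invariant-border
# experiment, and the simulated categorical/continuous responders that
# stand in for a trained network.

#' Probe training configuration
#'
#' @param n_train_per_class training samples per class (default 500).
#' @param n_val_per_class validation samples per class (default 50).
#' @param epochs training epochs (default 5); the best-validation epoch
#'   checkpoint is kept.
#' @param batch_size,lr,momentum minibatch SGD hyperparameters.
#' @param seed optional integer seed making the training reproducible.
#' @return a `probe_train_config`.
#' @export
probe_train_config <- function(n_train_per_class = 500L, n_val_per_class = 50L,
                               epochs = 5L, batch_size = 64L, lr = 0.5,
                               momentum = 0.9, seed = NULL) {
  stopifnot(n_train_per_class > 0, n_val_per_class > 0, epochs > 0)
  structure(list(n_train_per_class = n_train_per_class,
                 n_val_per_class = n_val_per_class, epochs = epochs,
                 batch_size = batch_size, lr = lr, momentum = momentum,
                 seed = seed),
            class = "probe_train_config")
}

#' Evaluation grid over the hue spectrum
#'
#' @param n_bins spectrum steps (default 100).
#' @param samples_per_bin freshly rendered samples classified at each bin
#'   center (default 60).
#' @return an `eval_grid`; the default yields 6000 classifications per
#'   row.
#' @export
eval_grid <- function(n_bins = 100L, samples_per_bin = 60L) {
  stopifnot(n_bins > 0, samples_per_bin > 0)
  structure(list(n_bins = as.integer(n_bins),
                 samples_per_bin = as.integer(samples_per_bin),
                 total = as.integer(n_bins) * as.integer(samples_per_bin)),
            class = "eval_grid")
}

#' Train a probe head on band-sampled word stimuli
#'
#' A single affine layer with softmax output is trained by minibatch SGD
#' with cross-entropy on `n_train_per_class` word stimuli per band;
#' validation after every epoch keeps the best checkpoint. The extractor
#' is never updated.
#'
#' @param ex a `feature_extractor`.
#' @param bands a `hueband_set` defining the K classes.
#' @param cfg a [probe_train_config()].
#' @param stim_cfg the [word_stimulus_config()] for rendering.
#' @param features optional function `hues -> feature matrix` overriding
#'   word-stimulus featurization (used by experiments with other stimulus
#'   types).
#' @return a `probe_head` with weights, `K`, `best_val` and `val_trace`.
#' @export
train_probe_head <- function(ex, bands, cfg = probe_train_config(),
                             stim_cfg = word_stimulus_config(),
                             features = NULL) {
  K <- bands$n_classes
  featurize <- if (is.null(features)) {
    function(hues) word_features(ex, hues, stim_cfg)
  } else {
    features
  }
  run <- function() {
    y_tr <- rep(0:(K - 1), each = cfg$n_train_per_class)
    y_va <- rep(0:(K - 1), each = cfg$n_val_per_class)
    h_tr <- unlist(lapply(0:(K - 1), function(k)
      sample_class_hue(bands, k, cfg$n_train_per_class)))
    h_va <- unlist(lapply(0:(K - 1), function(k)
      sample_class_hue(bands, k, cfg$n_val_per_class)))
    X_tr <- featurize(h_tr)
    X_va <- featurize(h_va)
    net <- mlp_train(X_tr, y_tr, K = K, hidden = 0L, epochs = cfg$epochs,
                     batch_size = cfg$batch_size, lr = cfg$lr,
                     momentum = cfg$momentum, Xval = X_va, yval = y_va)
    structure(list(W = net$W2, b = net$b2, K = K, dim = ncol(X_tr),
                   bands = bands, best_val = net$acc,
                   val_trace = net$val_trace, trained = TRUE),
              class = "probe_head")
  }
  if (is.null(cfg$seed)) run() else with_seed(cfg$seed, run())
}

#' @export
print.probe_head <- function(x, ...) {
  cat(sprintf("<probe_head> K = %d, D = %d, best val acc = %.3f\n",
              x$K, x$dim, x$best_val))
  invisible(x)
}

#' Predict 0-based class labels from a feature matrix
#' @param head a trained `probe_head`.
#' @param X feature matrix (rows = samples).
#' @return integer labels in `[0, K)`; ties go to the lowest index.
#' @export
predict_probe <- function(head, X) {
  if (!isTRUE(head$trained)) stop("probe head is not trained", call. = FALSE)
  logits <- sweep(X %*% head$W, 2, head$b, "+")
  as.integer(apply(logits, 1, which.max)) - 1L
}

# internal constructor for a spectrum-evaluation result
new_classification_row <- function(samples, bands, provenance = list()) {
  mode_row <- apply(samples, 2, column_mode)
  structure(list(samples = samples, mode_row = as.integer(mode_row),
                 n_bins = ncol(samples), K = bands$n_classes, bands = bands,
                 provenance = provenance),
            class = "classification_row")
}

#' @export
print.classification_row <- function(x, ...) {
  cat(sprintf("<classification_row> %d bins x %d samples, K = %d, %d transitions\n",
              x$n_bins, nrow(x$samples), x$K, length(find_transitions(x$mode_row))))
  invisible(x)
}

#' Evaluate a trained probe over the whole hue spectrum
#'
#' For every bin, `samples_per_bin` freshly rendered word stimuli at the
#' bin-center hue are classified; the per-column mode gives the mode row.
#'
#' @param head a trained `probe_head`.
#' @param ex the `feature_extractor` the head was trained on.
#' @param grid an [eval_grid()].
#' @param stim_cfg the [word_stimulus_config()] for rendering.
#' @return a `classification_row` (`samples` is
#'   `samples_per_bin x n_bins`, 0-based labels).
#' @export
evaluate_spectrum <- function(head, ex, grid = eval_grid(),
                              stim_cfg = word_stimulus_config()) {
  if (!isTRUE(head$trained)) stop("probe head is not trained", call. = FALSE)
  hues <- rep(bin_centers(grid$n_bins), each = grid$samples_per_bin)
  X <- word_features(ex, hues, stim_cfg)
  labels <- predict_probe(head, X)
  samples <- matrix(labels, nrow = grid$samples_per_bin, ncol = grid$n_bins)
  new_classification_row(samples, head$bands,
                         provenance = list(extractor = ex$name))
}

#' Design grid of the invariant-border experiment
#'
#' One row per training session: every class count crossed with every
#' band shift (`shift_i = (i - 1) / n_shifts` of the full circle).
#'
#' @param class_counts output-class counts (default 4:9).
#' @param n_shifts shifts per class count (default 150; the default
#'   design has 900 sessions).
#' @return data frame with columns `K`, `shift_index`, `shift`.
#' @export
invariant_design <- function(class_counts = 4:9, n_shifts = 150L) {
  d <- expand.grid(shift_index = seq_len(n_shifts), K = class_counts,
                   KEEP.OUT.ATTRS = FALSE)
  d$shift <- (d$shift_index - 1) / n_shifts
  d[, c("K", "shift_index", "shift")]
}

#' Run the shifting-band invariant-border experiment
#'
#' For each class count K and shift, a probe head is trained on the
#' shifted uniform band set and evaluated over the spectrum. Sessions
#' that fail to train are logged and excluded (their count is reported in
#' the `n_failed` attribute).
#'
#' @param ex a `feature_extractor`.
#' @param class_counts,n_shifts experiment design (defaults 4:9 and 150).
#' @param cfg a [probe_train_config()].
#' @param grid an [eval_grid()].
#' @param stim_cfg a [word_stimulus_config()].
#' @param total_width combined band width (default 0.2).
#' @param seed integer seed; each session derives its own seed.
#' @return list of `classification_row` (attributes `design`,
#'   `n_failed`).
#' @export
run_invariant_experiment <- function(ex, class_counts = 4:9, n_shifts = 150L,
                                     cfg = probe_train_config(),
                                     grid = eval_grid(),
                                     stim_cfg = word_stimulus_config(),
                                     total_width = 0.2, seed = 1L) {
  design <- invariant_design(class_counts, n_shifts)
  rows <- vector("list", nrow(design))
  failed <- 0L
  for (i in seq_len(nrow(design))) {
    K <- design$K[i]
    bands <- make_uniform_bands(K, design$shift[i], total_width)
    srow <- derive_seed(seed, K, design$shift_index[i])
    res <- tryCatch(
      with_seed(srow, {
        head <- train_probe_head(ex, bands, cfg, stim_cfg)
        evaluate_spectrum(head, ex, grid, stim_cfg)
      }),
      error = function(e) {
        message(sprintf("session K=%d shift=%d failed: %s",
                        K, design$shift_index[i], conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) failed <- failed + 1L else {
      res$provenance$K <- K
      res$provenance$shift <- design$shift[i]
      res$provenance$seed <- srow
    }
    rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  attr(rows, "design") <- design
  attr(rows, "n_failed") <- failed
  rows
}

## ---- simulated responders ---------------------------------------------

#' Categorical responder with planted borders
#'
#' Labels every hue with the class whose band center shares the hue's
#' planted category (nearest center when several classes share it); a
#' category holding no band center is generalized as a whole to the
#' class nearest its midpoint. Borders therefore sit at the planted
#' positions regardless of band shift.
#'
#' @param borders planted `border_set` or sorted positions.
#' @param label_noise per-sample probability of flipping the label to a
#'   uniformly chosen other class (default 0).
#' @return a `responder_model`.
#' @export
categorical_responder <- function(borders, label_noise = 0) {
  if (inherits(borders, "border_set")) borders <- borders$positions
  stopifnot(label_noise >= 0, label_noise < 1)
  structure(list(kind = "categorical", borders = sort(wrap_hue(borders)),
                 label_noise = label_noise),
            class = "responder_model")
}

#' Continuous (borderless) responder
#'
#' Labels every hue with the class of the circularly nearest band center,
#' so borders shift along with the training bands.
#'
#' @param label_noise per-sample flip probability (default 0).
#' @return a `responder_model`.
#' @export
continuous_responder <- function(label_noise = 0) {
  stopifnot(label_noise >= 0, label_noise < 1)
  structure(list(kind = "continuous", label_noise = label_noise),
            class = "responder_model")
}

# noise-free responder label for each hue
responder_labels <- function(model, hues, bands) {
  K <- bands$n_classes
  nearest <- function(h) {
    d <- circular_distance(h, bands$centers)
    which(d == min(d))[1] - 1L # ties to the lowest class index
  }
  if (model$kind == "continuous") {
    return(vapply(hues, nearest, integer(1)))
  }
  if (model$kind != "categorical") stop("unknown responder kind", call. = FALSE)
  borders <- model$borders
  center_cat <- planted_category(bands$centers, borders)
  hue_cat <- planted_category(hues, borders)
  # a category holding no band center is generalized as a whole to the
  # class nearest its midpoint, keeping transitions pinned to borders
  n_cat <- length(borders)
  nxt <- c(borders[-1], borders[1] + 1)
  mids <- wrap_hue((borders + nxt) / 2)
  empty_label <- vapply(seq_len(n_cat), function(c) {
    d <- circular_distance(mids[c], bands$centers)
    which(d == min(d))[1] - 1L
  }, integer(1))
  vapply(seq_along(hues), function(i) {
    cand <- which(center_cat == hue_cat[i])
    if (length(cand) == 0L) return(empty_label[hue_cat[i] + 1L])
    d <- circular_distance(hues[i], bands$centers[cand])
    cand[which(d == min(d))[1]] - 1L
  }, integer(1))
}

#' Simulate a classification row from a responder model
#'
#' Each evaluation hue gets its responder label; every sample is then
#' independently flipped to a uniform other class with probability
#' `label_noise`.
#'
#' @param model a `responder_model`.
#' @param bands the `hueband_set` the virtual probe was "trained" on.
#' @param grid an [eval_grid()].
#' @param seed optional seed for the noise draws.
#' @return a `classification_row`.
#' @export
simulate_row <- function(model, bands, grid = eval_grid(), seed = NULL) {
  run <- function() {
    base <- responder_labels(model, bin_centers(grid$n_bins), bands)
    samples <- matrix(rep(base, each = grid$samples_per_bin),
                      nrow = grid$samples_per_bin)
    eps <- model$label_noise
    if (eps > 0) {
      K <- bands$n_classes
      flip <- stats::runif(length(samples)) < eps
      if (any(flip)) {
        bump <- sample.int(K - 1, sum(flip), replace = TRUE)
        samples[flip] <- (samples[flip] + bump) %% K
      }
    }
    new_classification_row(samples, bands,
                           provenance = list(responder = model$kind))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a full shifting-band stack from a responder model
#'
#' Responder-model analogue of [run_invariant_experiment()]: no training,
#' one simulated row per (K, shift) cell.
#'
#' @param model a `responder_model`.
#' @param class_counts,n_shifts design (defaults 4:9, 150).
#' @param grid an [eval_grid()].
#' @param total_width combined band width (default 0.2).
#' @param seed integer seed.
#' @return list of `classification_row` with a `design` attribute.
#' @export
simulate_row_stack <- function(model, class_counts = 4:9, n_shifts = 150L,
                               grid = eval_grid(), total_width = 0.2,
                               seed = 1L) {
  design <- invariant_design(class_counts, n_shifts)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    bands <- make_uniform_bands(design$K[i], design$shift[i], total_width)
    rows[[i]] <- simulate_row(model, bands, grid,
                              seed = derive_seed(seed, design$K[i],
                                                 design$shift_index[i]))
  }
  attr(rows, "design") <- design
  rows
}
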