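# The FeatureExtractor contract and its reference implementations: an
# analytic mean-glyph-RGB responder and a small scratch-trained backbone
# (one-hidden-layer dense network on block-downsampled pixels, trained
# end-to-end by the package's own minibatch SGD). Extractors may expose a
# fast word-stimulus path that computes features analytically; it draws
# fonts and positions from the RNG in exactly the same order as
# render_word_stimulus, so render-then-extract and the fast path agree
# bit for bit under the same seed.

#' Construct a feature extractor
#'
#' @param name extractor name.
#' @param dim feature dimension D.
#' @param extract function `raster -> numeric(dim)`; must be
#'   deterministic in the image.
#' @param word_batch optional fast path `function(hues, cfg) -> matrix`
#'   (`length(hues) x dim`) equivalent to rendering word stimuli and
#'   extracting.
#' @param meta free-form metadata list.
#' @return a `feature_extractor`.
#' @export
feature_extractor <- function(name, dim, extract, word_batch = NULL,
                              meta = list()) {
  structure(list(name = name, dim = as.integer(dim), extract = extract,
                 word_batch = word_batch, meta = meta),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %s (D = %d)\n", x$name, x$dim))
  invisible(x)
}

#' Extract features from one raster
#' @param ex a `feature_extractor`.
#' @param img raster array in `[0, 255]`.
#' @return numeric vector of length `ex$dim`.
#' @export
extract_features <- function(ex, img) {
  as.numeric(ex$extract(img))
}

# features for word stimuli at the given hues: fast path when available,
# otherwise render and extract
word_features <- function(ex, hues, cfg) {
  if (!is.null(ex$word_batch)) return(ex$word_batch(hues, cfg))
  t(vapply(hues, function(h) extract_features(ex, render_word_stimulus(h, cfg)),
           numeric(ex$dim)))
}

#' Analytic mean-glyph-RGB extractor
#'
#' D = 3 reference extractor: the mean RGB (on the `[0, 1]` scale) of all
#' pixels that differ from the configured background. For word stimuli
#' this is exactly the quantized glyph color, which makes band classes
#' linearly separable.
#'
#' @param cfg the [word_stimulus_config()] whose background defines
#'   non-glyph pixels.
#' @return a `feature_extractor` with a fast word path.
#' @export
mean_glyph_rgb_extractor <- function(cfg = word_stimulus_config()) {
  bg <- cfg$background
  extract <- function(img) {
    glyph <- img[, , 1] != bg[1] | img[, , 2] != bg[2] | img[, , 3] != bg[3]
    if (!any(glyph)) stop("no non-background pixels", call. = FALSE)
    c(mean(img[, , 1][glyph]), mean(img[, , 2][glyph]),
      mean(img[, , 3][glyph])) / 255
  }
  word_batch <- function(hues, wcfg = cfg) {
    out <- matrix(0, length(hues), 3)
    for (i in seq_along(hues)) {
      place_word(wcfg) # consume RNG exactly as render_word_stimulus would
      out[i, ] <- rgb_to_8bit(hue_to_rgb(hues[i]))[1, ] / 255
    }
    out
  }
  feature_extractor("mean_glyph_rgb", 3L, extract, word_batch)
}

# block-average matrix mapping `size` pixels onto `grid` cells
ds_matrix <- function(size, grid) {
  breaks <- floor(seq(0, size, length.out = grid + 1))
  P <- matrix(0, grid, size)
  for (i in seq_len(grid)) {
    cols <- (breaks[i] + 1):breaks[i + 1]
    P[i, cols] <- 1 / length(cols)
  }
  P
}

## ---- minimal dense network with minibatch SGD -------------------------

# stable softmax cross-entropy; rows of `logits` are samples
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# dense softmax classifier with 0 or more tanh hidden layers, trained
# by minibatch SGD with momentum; per-epoch validation selects the
# returned weights ("best network" checkpointing). `hidden` is a vector
# of hidden widths (length 0 gives a pure affine head). For heads the
# code keeps the W2/b2 naming of the output layer.
mlp_train <- function(X, y, K, hidden = integer(0), epochs = 5L,
                      batch_size = 64L, lr = 0.2, momentum = 0.9,
                      Xval = NULL, yval = NULL) {
  hidden <- hidden[hidden > 0]
  n <- nrow(X)
  widths <- c(ncol(X), hidden, K)
  L <- length(widths) - 1L # number of weight layers; layer L is softmax
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  W <- lapply(seq_len(L), function(i) init(widths[i], widths[i + 1]))
  bvec <- lapply(seq_len(L), function(i) numeric(widths[i + 1]))
  vW <- lapply(W, function(w) w * 0)
  vb <- lapply(bvec, function(b) b * 0)
  forward <- function(X, W, bvec) {
    A <- vector("list", L + 1L)
    A[[1]] <- X
    for (i in seq_len(L)) {
      Z <- sweep(A[[i]] %*% W[[i]], 2, bvec[[i]], "+")
      A[[i + 1]] <- if (i < L) tanh(Z) else Z
    }
    A
  }
  val_acc <- function(W, bvec) {
    lg <- forward(Xval, W, bvec)[[L + 1L]]
    mean(max.col(lg, ties.method = "first") - 1L == yval)
  }
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y + 1L)] <- 1
  best <- list(W = W, bvec = bvec, acc = -Inf)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      bidx <- idx[start:min(start + batch_size - 1, n)]
      Xb <- X[bidx, , drop = FALSE]; Yb <- Y[bidx, , drop = FALSE]
      m <- length(bidx)
      A <- forward(Xb, W, bvec)
      delta <- (softmax_rows(A[[L + 1L]]) - Yb) / m
      for (i in L:1) {
        gW <- crossprod(A[[i]], delta)
        gb <- colSums(delta)
        if (i > 1) delta <- (delta %*% t(W[[i]])) * (1 - A[[i]]^2)
        vW[[i]] <- momentum * vW[[i]] - lr * gW
        vb[[i]] <- momentum * vb[[i]] - lr * gb
        W[[i]] <- W[[i]] + vW[[i]]
        bvec[[i]] <- bvec[[i]] + vb[[i]]
      }
      if (!all(is.finite(W[[L]]))) {
        stop("non-finite weights during training (lr too high?)", call. = FALSE)
      }
    }
    trace[ep] <- val_acc(W, bvec)
    if (trace[ep] > best$acc) best <- list(W = W, bvec = bvec, acc = trace[ep])
  }
  list(W = best$W, bvec = best$bvec, acc = best$acc,
       W2 = best$W[[L]], b2 = best$bvec[[L]],
       val_trace = trace, hidden = hidden, n_layers = L)
}

# hidden activations of the penultimate layer for a trained mlp
mlp_penultimate <- function(net, X) {
  A <- X
  L <- net$n_layers
  for (i in seq_len(L - 1L)) {
    A <- tanh(sweep(A %*% net$W[[i]], 2, net$bvec[[i]], "+"))
  }
  A
}

#' Planted category of a hue
#'
#' Categories are the circular intervals between consecutive planted
#' borders: category `j` (0-based) spans `[pos[j+1], pos[j+2])`, with the
#' last category wrapping from the last border back to the first.
#'
#' @param h hue vector.
#' @param positions sorted border positions (a `border_set` or numeric).
#' @return 0-based category indices.
#' @export
planted_category <- function(h, positions) {
  if (inherits(positions, "border_set")) positions <- positions$positions
  idx <- findInterval(wrap_hue(h), positions)
  idx[idx == 0L] <- length(positions)
  idx - 1L
}

#' Train a scratch backbone on planted color categories
#'
#' A small dense network (one tanh hidden layer over block-downsampled,
#' normalized pixels) is trained end-to-end to classify word stimuli into
#' the planted categories; its frozen hidden layer is returned as a
#' FeatureExtractor. Hues are drawn uniformly over the whole spectrum and
#' labeled by planted category. Training must reach the validation
#' criterion or an error is raised.
#'
#' @param planted a `border_set` (or sorted positions) defining the
#'   categories.
#' @param cfg [word_stimulus_config()] for the training stimuli.
#' @param grid_size downsampling grid side (default 16; D_in = 768).
#' @param hidden vector of hidden-layer widths; the last entry is the
#'   penultimate width, the extractor dimension. Defaults to a wide
#'   first layer followed by a penultimate as wide as the category
#'   count: depth irons out input-space kinks (the RGB cube corners)
#'   inside broad categories, and the narrow penultimate yields a
#'   compactly categorical representation; wider penultimates retain
#'   continuous hue information that re-splits broad categories under
#'   probing.
#' @param n_train,n_val training/validation sample counts (defaults
#'   6000 and 800).
#' @param epochs,batch_size,lr,momentum SGD hyperparameters.
#' @param acc_criterion minimum best validation accuracy (default 0.95).
#' @param restarts additional training attempts with derived seeds when
#'   an attempt misses the criterion (default 2); the error is raised
#'   only after all attempts fail.
#' @param seed integer seed; the whole training is reproducible.
#' @return a `feature_extractor` with `dim = hidden` and a fast word
#'   path.
#' @export
make_scratch_category_backbone <- function(planted,
                                           cfg = word_stimulus_config(),
                                           grid_size = 16L, hidden = NULL,
                                           n_train = 6000L, n_val = 800L,
                                           epochs = 250L, batch_size = 64L,
                                           lr = 0.1, momentum = 0.9,
                                           acc_criterion = 0.95,
                                           restarts = 2L, seed = 1L) {
  if (inherits(planted, "border_set")) planted <- planted$positions
  if (is.null(hidden)) hidden <- c(32L, length(planted))
  imn <- c(0.485, 0.456, 0.406); isd <- c(0.229, 0.224, 0.225)
  Pr <- ds_matrix(cfg$height, grid_size)
  Pc <- ds_matrix(cfg$width, grid_size)
  bg <- cfg$background

  # downsampled, normalized input for one word placement; exact linear
  # shortcut: block-averaging the raster equals averaging the glyph mask
  ds_word_input <- function(hue, p) {
    col8 <- rgb_to_8bit(hue_to_rgb(hue))[1, ]
    rr <- p$row0:(p$row0 + nrow(p$mask) - 1)
    cc <- p$col0:(p$col0 + ncol(p$mask) - 1)
    mds <- (Pr[, rr, drop = FALSE] %*% p$mask) %*% t(Pc[, cc, drop = FALSE])
    x <- numeric(3 * grid_size^2)
    for (ch in 1:3) {
      plane <- (bg[ch] + (col8[ch] - bg[ch]) * mds) / 255
      x[((ch - 1) * grid_size^2 + 1):(ch * grid_size^2)] <-
        (plane - imn[ch]) / isd[ch]
    }
    x
  }
  ds_raster_input <- function(img) {
    x <- numeric(3 * grid_size^2)
    for (ch in 1:3) {
      plane <- (Pr %*% img[, , ch] %*% t(Pc)) / 255
      x[((ch - 1) * grid_size^2 + 1):(ch * grid_size^2)] <-
        (plane - imn[ch]) / isd[ch]
    }
    x
  }
  input_batch <- function(hues) {
    t(vapply(hues, function(h) ds_word_input(h, place_word(cfg)),
             numeric(3 * grid_size^2)))
  }

  net <- NULL
  for (attempt in 0:restarts) {
    s <- if (attempt == 0L) seed else derive_seed(seed, 7000L + attempt)
    cand <- with_seed(s, {
      h_tr <- stats::runif(n_train); y_tr <- planted_category(h_tr, planted)
      h_va <- stats::runif(n_val);   y_va <- planted_category(h_va, planted)
      X_tr <- input_batch(h_tr); X_va <- input_batch(h_va)
      mlp_train(X_tr, y_tr, K = length(planted), hidden = hidden,
                epochs = epochs, batch_size = batch_size, lr = lr,
                momentum = momentum, Xval = X_va, yval = y_va)
    })
    if (is.null(net) || cand$acc > net$acc) net <- cand
    if (net$acc >= acc_criterion) break
  }
  if (net$acc < acc_criterion) {
    stop(sprintf("backbone failed the validation criterion (%.3f < %.2f)",
                 net$acc, acc_criterion), call. = FALSE)
  }
  hidden_of <- function(X) mlp_penultimate(net, X)
  feature_extractor(
    name = "scratch_category_backbone",
    dim = utils::tail(hidden, 1),
    extract = function(img) hidden_of(matrix(ds_raster_input(img), 1))[1, ],
    word_batch = function(hues, wcfg = cfg) hidden_of(input_batch(hues)),
    meta = list(planted = planted, grid_size = grid_size,
                val_acc = net$acc, val_trace = net$val_trace, seed = seed)
  )
}
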