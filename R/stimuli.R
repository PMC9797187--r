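# Synthetic stimulus generation: colored-word rasters, multi-word
# distractor scenes, enclosure-filled outline shapes, image
# normalization and PNG/manifest I/O.
#
# Rasters are numeric arrays of dim c(height, width, 3) holding 8-bit
# values in [0, 255]. Glyph rendering is binary (no anti-aliasing), so a
# word stimulus contains exactly the glyph color and the background.

#' Word stimulus configuration
#'
#' @param word the word drawn into every image (default "color").
#' @param font_size nominal font size in points (default 40; the rendered
#'   word is roughly 100 x 25 pixels).
#' @param fonts pool of packaged font identifiers (default all 5).
#' @param background 8-bit RGB background (default mid-grey 128).
#' @param width,height raster size in pixels (default 224 x 224).
#' @return a `word_stimulus_config` list.
#' @export
word_stimulus_config <- function(word = "color", font_size = 40,
                                 fonts = font_names(),
                                 background = c(128, 128, 128),
                                 width = 224, height = 224) {
  stopifnot(length(background) == 3, all(background >= 0), all(background <= 255))
  structure(list(word = word, font_size = font_size, fonts = fonts,
                 background = background, width = width, height = height),
            class = "word_stimulus_config")
}

blank_raster <- function(width, height, rgb8) {
  img <- array(0, dim = c(height, width, 3))
  img[, , 1] <- rgb8[1]; img[, , 2] <- rgb8[2]; img[, , 3] <- rgb8[3]
  img
}

# draw a glyph mask onto img at (row0, col0) in the given 8-bit color
draw_mask <- function(img, mask, row0, col0, rgb8) {
  rows <- row0:(row0 + nrow(mask) - 1)
  cols <- col0:(col0 + ncol(mask) - 1)
  for (ch in 1:3) {
    sub <- img[rows, cols, ch]
    sub[mask] <- rgb8[ch]
    img[rows, cols, ch] <- sub
  }
  img
}

# uniform placement of a mask inside the raster; also returns the mask
place_word <- function(cfg) {
  font <- cfg$fonts[sample.int(length(cfg$fonts), 1)]
  mask <- word_mask(cfg$word, font, cfg$font_size)
  if (nrow(mask) > cfg$height || ncol(mask) > cfg$width) {
    stop("word does not fit in the raster at this font size", call. = FALSE)
  }
  list(mask = mask, font = font,
       row0 = sample.int(cfg$height - nrow(mask) + 1, 1),
       col0 = sample.int(cfg$width - ncol(mask) + 1, 1))
}

#' Render a single-word color stimulus
#'
#' The word is drawn at a random position in a random pool font; all
#' glyph pixels carry `hue_to_rgb(hue)` quantized to 8 bits, all other
#' pixels the background color.
#'
#' @param hue glyph hue in `[0, 1)`.
#' @param cfg a [word_stimulus_config()].
#' @return raster array `height x width x 3` in `[0, 255]`.
#' @export
render_word_stimulus <- function(hue, cfg = word_stimulus_config()) {
  img <- blank_raster(cfg$width, cfg$height, cfg$background)
  p <- place_word(cfg)
  draw_mask(img, p$mask, p$row0, p$col0, rgb_to_8bit(hue_to_rgb(hue))[1, ])
}

#' Render a multi-word stimulus with distractors
#'
#' Three target words at the target hue (full saturation/brightness),
#' then two distractor words at independently drawn random hues, drawn
#' on top; the background is a random hue at 50% brightness. All word
#' positions and fonts are random.
#'
#' @param target_hue hue of the three target words.
#' @param cfg a [word_stimulus_config()] (its `background` is ignored).
#' @return raster array with attributes `distractor_hues` and
#'   `background_hue`.
#' @export
render_multiword_stimulus <- function(target_hue, cfg = word_stimulus_config()) {
  bg_hue <- stats::runif(1)
  bg8 <- rgb_to_8bit(hue_to_rgb(bg_hue) * 0.5)[1, ]
  img <- blank_raster(cfg$width, cfg$height, bg8)
  tgt8 <- rgb_to_8bit(hue_to_rgb(target_hue))[1, ]
  for (i in 1:3) {
    p <- place_word(cfg)
    img <- draw_mask(img, p$mask, p$row0, p$col0, tgt8)
  }
  distractors <- stats::runif(2)
  for (d in distractors) {
    p <- place_word(cfg)
    img <- draw_mask(img, p$mask, p$row0, p$col0, rgb_to_8bit(hue_to_rgb(d))[1, ])
  }
  attr(img, "distractor_hues") <- distractors
  attr(img, "background_hue") <- bg_hue
  img
}

#' Enclosure mask of a line drawing
#'
#' A pixel is enclosed iff a line pixel exists strictly to its left in
#' the same row, strictly to its right, strictly above it in the same
#' column and strictly below it. Line pixels themselves are excluded
#' from the fill mask.
#'
#' @param outline logical matrix, `TRUE` at line pixels.
#' @return logical matrix of enclosed pixels (all `FALSE` for an empty
#'   outline).
#' @export
enclosure_mask <- function(outline) {
  storage.mode(outline) <- "logical"
  csr <- t(apply(outline, 1, cumsum))                  # inclusive row cumsum
  left <- (csr - outline) > 0                          # strictly left
  csr_rev <- t(apply(outline[, ncol(outline):1, drop = FALSE], 1, cumsum))
  right <- ((csr_rev - outline[, ncol(outline):1, drop = FALSE]) > 0)[
    , ncol(outline):1, drop = FALSE]
  csc <- apply(outline, 2, cumsum)
  above <- (csc - outline) > 0
  csc_rev <- apply(outline[nrow(outline):1, , drop = FALSE], 2, cumsum)
  below <- ((csc_rev - outline[nrow(outline):1, , drop = FALSE]) > 0)[
    nrow(outline):1, , drop = FALSE]
  left & right & above & below & !outline
}

#' Render an outline shape filled with a spectrum hue
#'
#' The enclosure mask is painted in `hue_to_rgb(fill_hue)`, then the
#' drawn lines are overdrawn on top.
#'
#' @param outline logical line mask (already at stroke thickness).
#' @param fill_hue fill hue in `[0, 1)`.
#' @param line_rgb 8-bit line color (default black).
#' @param background 8-bit background (default mid-grey).
#' @return raster array `nrow x ncol x 3`.
#' @export
render_filled_shape <- function(outline, fill_hue, line_rgb = c(0, 0, 0),
                                background = c(128, 128, 128)) {
  fill <- enclosure_mask(outline)
  img <- blank_raster(ncol(outline), nrow(outline), background)
  f8 <- rgb_to_8bit(hue_to_rgb(fill_hue))[1, ]
  for (ch in 1:3) {
    sub <- img[, , ch]
    sub[fill] <- f8[ch]
    sub[outline] <- line_rgb[ch]
    img[, , ch] <- sub
  }
  img
}

#' Names of the synthetic outline families
#'
#' Fourteen closed-shape families (one per object class in the colored
#' objects experiment): simple convex shapes, stars, Fourier blobs and
#' multi-lobe forms, all with clear outer borders and large enclosed
#' interiors.
#'
#' @return character vector of 14 family names.
#' @export
shape_families <- function() {
  c("ellipse", "circle", "rectangle", "triangle", "diamond", "pentagon",
    "hexagon", "star5", "star6", "blob3", "blob4", "blob5", "peanut", "egg")
}

# dense boundary points (unit scale, centered) for one family draw
shape_boundary <- function(family, n_pts = 3000) {
  th <- seq(0, 2 * pi, length.out = n_pts)
  rot <- stats::runif(1, 0, 2 * pi)
  poly_r <- function(k) {
    # radius profile of a regular k-gon traced by angle
    1 / cos((th %% (2 * pi / k)) - pi / k) * cos(pi / k)
  }
  r <- switch(family,
    ellipse = {
      a <- stats::runif(1, 0.7, 1); b <- stats::runif(1, 0.45, 0.7)
      ab <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
      ab
    },
    circle = rep(stats::runif(1, 0.8, 1), length(th)),
    rectangle = {
      a <- stats::runif(1, 0.8, 1); b <- stats::runif(1, 0.45, 0.7)
      pmin(abs(a / cos(th)), abs(b / sin(th)))
    },
    triangle = poly_r(3),
    diamond = poly_r(4),
    pentagon = poly_r(5),
    hexagon = poly_r(6),
    star5 = 0.62 + 0.38 * cos(5 * th),
    star6 = 0.68 + 0.32 * cos(6 * th),
    blob3 = 0.8 + stats::runif(1, 0.08, 0.18) * cos(3 * th + stats::runif(1, 0, 2 * pi)),
    blob4 = 0.8 + stats::runif(1, 0.08, 0.16) * cos(4 * th + stats::runif(1, 0, 2 * pi)),
    blob5 = 0.8 + stats::runif(1, 0.06, 0.14) * cos(5 * th + stats::runif(1, 0, 2 * pi)),
    peanut = 0.62 + 0.3 * cos(2 * th)^2,
    egg = 0.78 * (1 + 0.18 * sin(th)),
    stop("unknown shape family: ", family, call. = FALSE)
  )
  cbind(x = r * cos(th + rot), y = r * sin(th + rot))
}

#' Generate a synthetic closed-outline raster
#'
#' Draws one random instance of the family as a closed stroke at the
#' requested thickness. Degenerate draws (enclosed area outside
#' [min_area, max_area] of the raster) are regenerated up to a retry cap.
#'
#' @param family one of [shape_families()].
#' @param size raster side in pixels (default 224).
#' @param thickness stroke thickness in pixels (default 4).
#' @param min_area,max_area acceptable enclosed-area fraction
#'   (defaults 0.05 and 0.80).
#' @param max_tries regeneration cap (default 20).
#' @return logical `size x size` outline matrix.
#' @export
generate_synthetic_outline <- function(family, size = 224, thickness = 4,
                                       min_area = 0.05, max_area = 0.80,
                                       max_tries = 20) {
  for (try in seq_len(max_tries)) {
    pts <- shape_boundary(family)
    scale <- stats::runif(1, 0.28, 0.42) * size
    cx <- size / 2 + stats::runif(1, -0.06, 0.06) * size
    cy <- size / 2 + stats::runif(1, -0.06, 0.06) * size
    rows <- round(cy + pts[, "y"] * scale)
    cols <- round(cx + pts[, "x"] * scale)
    keep <- rows >= 1 & rows <= size - thickness + 1 &
      cols >= 1 & cols <= size - thickness + 1
    rows <- rows[keep]; cols <- cols[keep]
    if (length(rows) < 10) next
    m <- matrix(FALSE, size, size)
    # stamp a thickness x thickness block at every path pixel
    for (dr in 0:(thickness - 1)) {
      for (dc in 0:(thickness - 1)) {
        m[cbind(rows + dr, cols + dc)] <- TRUE
      }
    }
    frac <- sum(enclosure_mask(m)) / (size * size)
    if (frac >= min_area && frac <= max_area) return(m)
  }
  stop("failed to generate a non-degenerate ", family, " outline in ",
       max_tries, " tries", call. = FALSE)
}

#' Normalize a raster to a zero-centered tensor
#'
#' Per-channel `(value/255 - mean) / sd`. Defaults are the conventional
#' ImageNet constants; the transform is invertible given the constants.
#'
#' @param img raster array in `[0, 255]`.
#' @param mean,sd per-channel constants.
#' @return numeric array of the same shape.
#' @export
normalize_image <- function(img, mean = c(0.485, 0.456, 0.406),
                            sd = c(0.229, 0.224, 0.225)) {
  if (any(sd == 0)) stop("zero SD in normalization constants", call. = FALSE)
  out <- img / 255
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - mean[ch]) / sd[ch]
  out
}

#' Invert [normalize_image()]
#' @param img normalized array.
#' @param mean,sd the constants used to normalize.
#' @return raster-scale array in `[0, 255]` (not rounded).
#' @export
denormalize_image <- function(img, mean = c(0.485, 0.456, 0.406),
                              sd = c(0.229, 0.224, 0.225)) {
  out <- img
  for (ch in 1:3) out[, , ch] <- (out[, , ch] * sd[ch] + mean[ch]) * 255
  out
}

#' Write a raster to PNG
#' @param img raster array in `[0, 255]`.
#' @param path output file.
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Read a PNG back as a raster array
#' @param path PNG file.
#' @return raster array in `[0, 255]`.
#' @export
read_stimulus_png <- function(path) {
  img <- png::readPNG(path)
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Generate a batch of word stimuli with a manifest
#'
#' Renders one PNG per requested sample and writes a CSV manifest
#' (filename, class index, sampled hue, seed) alongside.
#'
#' @param dir output directory (created if needed).
#' @param bands a `hueband_set`; one sample is drawn per entry of
#'   `class_indices`.
#' @param class_indices 0-based class labels to sample.
#' @param cfg a [word_stimulus_config()].
#' @param seed integer seed for the whole batch.
#' @return the manifest data frame, invisibly.
#' @export
generate_stimulus_batch <- function(dir, bands, class_indices,
                                    cfg = word_stimulus_config(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- with_seed(seed, {
    rows <- lapply(seq_along(class_indices), function(i) {
      k <- class_indices[i]
      h <- sample_class_hue(bands, k)
      fn <- sprintf("stim_%04d_class%d.png", i, k)
      write_stimulus_png(render_word_stimulus(h, cfg), file.path(dir, fn))
      data.frame(filename = fn, class_index = k, hue = h, seed = seed)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
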