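# Packaged bitmap fonts for word stimuli. Glyphs are binary 5x7 pixel
# masks rendered without anti-aliasing, so every glyph pixel carries
# exactly the target color. Five font variants are derived from one base
# alphabet (regular, bold, slant, narrow, serif), giving distinct pixel
# masks while keeping rendering environment-independent.

.hc_base_glyphs <- local({
  g <- list(
    c = c(".###.",
          "#...#",
          "#....",
          "#....",
          "#....",
          "#...#",
          ".###."),
    o = c(".###.",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          ".###."),
    l = c("#....",
          "#....",
          "#....",
          "#....",
          "#....",
          "#....",
          "#####"),
    r = c("####.",
          "#...#",
          "#...#",
          "####.",
          "#.#..",
          "#..#.",
          "#...#"),
    e = c("#####",
          "#....",
          "#....",
          "####.",
          "#....",
          "#....",
          "#####"),
    d = c("####.",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          "####."),
    a = c(".###.",
          "#...#",
          "#...#",
          "#####",
          "#...#",
          "#...#",
          "#...#"),
    t = c("#####",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "..#.."),
    s = c(".####",
          "#....",
          "#....",
          ".###.",
          "....#",
          "....#",
          "####."),
    i = c("#####",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "..#..",
          "#####"),
    n = c("#...#",
          "##..#",
          "#.#.#",
          "#.#.#",
          "#..##",
          "#...#",
          "#...#"),
    u = c("#...#",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          "#...#",
          ".###.")
  )
  lapply(g, function(rows) {
    m <- do.call(rbind, lapply(strsplit(rows, ""), function(x) x == "#"))
    unname(m)
  })
})

# shift a logical matrix right by k columns, padding with FALSE
shift_right <- function(m, k) {
  if (k == 0) return(m)
  cbind(matrix(FALSE, nrow(m), k), m)[, seq_len(ncol(m)), drop = FALSE]
}

# derive a font (list of glyph masks) from the base alphabet
make_font <- function(style) {
  lapply(.hc_base_glyphs, function(m) {
    switch(style,
      regular = m,
      bold = m | shift_right(m, 1),
      slant = {
        out <- cbind(m, matrix(FALSE, nrow(m), 2))
        for (i in seq_len(nrow(m))) {
          out[i, ] <- shift_right(out[i, , drop = FALSE], (nrow(m) - i) %/% 3)
        }
        out
      },
      narrow = m[, -4, drop = FALSE],
      serif = {
        out <- m
        dil <- m | shift_right(m, 1) | cbind(m[, -1, drop = FALSE], FALSE)
        out[1, ] <- dil[1, ]
        out[nrow(m), ] <- dil[nrow(m), ]
        out
      },
      stop("unknown font style: ", style, call. = FALSE)
    )
  })
}

.hc_fonts <- local({
  styles <- c("regular", "bold", "slant", "narrow", "serif")
  stats::setNames(lapply(styles, make_font), styles)
})

#' Names of the packaged bitmap fonts
#' @return character vector of 5 font identifiers.
#' @export
font_names <- function() names(.hc_fonts)

#' Render a word as a binary glyph mask
#'
#' Glyphs are laid out left to right with a one-column gap and scaled by
#' integer pixel replication so that the glyph height approximates 70% of
#' the nominal font size (size 40 gives a word raster of roughly
#' 100 x 25 pixels for "color", depending on the font).
#'
#' @param word lowercase word; every letter must exist in the packaged
#'   alphabet.
#' @param font one of [font_names()].
#' @param font_size nominal size in points (default 40).
#' @return logical matrix, `TRUE` at glyph pixels.
#' @export
word_mask <- function(word, font = "regular", font_size = 40) {
  key <- paste(word, font, font_size, sep = "|")
  cached <- .hc_mask_cache[[key]]
  if (!is.null(cached)) return(cached)
  glyphs <- .hc_fonts[[font]]
  if (is.null(glyphs)) stop("unknown font: ", font, call. = FALSE)
  letters_ <- strsplit(tolower(word), "")[[1]]
  missing <- setdiff(letters_, names(glyphs))
  if (length(missing) > 0) {
    stop("glyphs not in packaged alphabet: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mats <- glyphs[letters_]
  gap <- matrix(FALSE, nrow(mats[[1]]), 1)
  pieces <- list(mats[[1]])
  for (m in mats[-1]) pieces <- c(pieces, list(gap, m))
  base <- do.call(cbind, pieces)
  scale <- max(1L, as.integer(round(font_size * 0.7 / nrow(base))))
  out <- (base %x% matrix(1, scale, scale)) > 0
  .hc_mask_cache[[key]] <- out
  out
}

.hc_mask_cache <- new.env(parent = emptyenv())
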