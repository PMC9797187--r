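# Circular hue arithmetic on the HSV hue circle, parameterized as a
# fraction in [0, 1). All arithmetic wraps modulo 1; all file outputs
# record fractions, never degrees.

#' Wrap values onto the hue circle
#'
#' @param h numeric vector; any real values.
#' @return values wrapped into `[0, 1)`.
#' @export
wrap_hue <- function(h) {
  out <- h %% 1
  # guard against 1 - eps rounding up to exactly 1
  out[out >= 1] <- 0
  out
}

#' Convert hue to RGB at full saturation and brightness
#'
#' Standard HSV to RGB conversion with saturation = value = 1, i.e. the
#' edges of the RGB cube. Piecewise linear and continuous in `h`.
#'
#' @param h numeric vector of hues in `[0, 1)`.
#' @return a matrix with columns `r`, `g`, `b`, each channel in `[0, 1]`.
#' @examples
#' hue_to_rgb(0)     # red
#' hue_to_rgb(1 / 3) # green
#' @export
hue_to_rgb <- function(h) {
  if (any(!is.finite(h)) || any(h < 0) || any(h >= 1)) {
    stop("hue values must be finite and in [0, 1)", call. = FALSE)
  }
  x <- h * 6
  sector <- floor(x)
  f <- x - sector
  r <- g <- b <- numeric(length(h))
  i0 <- sector == 0; i1 <- sector == 1; i2 <- sector == 2
  i3 <- sector == 3; i4 <- sector == 4; i5 <- sector == 5
  r[i0] <- 1;        g[i0] <- f[i0];     b[i0] <- 0
  r[i1] <- 1 - f[i1]; g[i1] <- 1;        b[i1] <- 0
  r[i2] <- 0;        g[i2] <- 1;         b[i2] <- f[i2]
  r[i3] <- 0;        g[i3] <- 1 - f[i3]; b[i3] <- 1
  r[i4] <- f[i4];    g[i4] <- 0;         b[i4] <- 1
  r[i5] <- 1;        g[i5] <- 0;         b[i5] <- 1 - f[i5]
  cbind(r = r, g = g, b = b)
}

#' Recover the hue of a full-saturation spectrum color
#'
#' Inverse of [hue_to_rgb()] for colors on the spectrum (at least one
#' channel 1 and at least one channel 0).
#'
#' @param rgb matrix with columns r, g, b in `[0, 1]`.
#' @return numeric vector of hues in `[0, 1)`.
#' @export
rgb_to_hue <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3)
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  if (any(d <= 0)) stop("achromatic color has no hue", call. = FALSE)
  h <- numeric(nrow(rgb))
  im <- mx == r
  h[im] <- ((g[im] - b[im]) / d[im]) / 6
  im <- mx == g & !(mx == r)
  h[im] <- (2 + (b[im] - r[im]) / d[im]) / 6
  im <- mx == b & !(mx == r) & !(mx == g)
  h[im] <- (4 + (r[im] - g[im]) / d[im]) / 6
  wrap_hue(h)
}

#' Circular distance between hues
#'
#' @param a,b hue vectors (recycled).
#' @return `min(|a - b|, 1 - |a - b|)`, in `[0, 0.5]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs(wrap_hue(a) - wrap_hue(b))
  pmin(d, 1 - d)
}

#' Weighted circular mean of hues
#'
#' Hues are mapped to unit-circle angles, the weighted resultant vector is
#' computed, and its angle mapped back to `[0, 1)`.
#'
#' @param hues hue vector.
#' @param weights nonnegative weights, same length (default equal).
#' @return a single hue in `[0, 1)`.
#' @export
circular_weighted_mean <- function(hues, weights = NULL) {
  if (length(hues) == 0L) stop("no hues supplied", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(hues))
  if (length(weights) != length(hues) || any(weights < 0)) {
    stop("weights must be nonnegative and match hues in length", call. = FALSE)
  }
  if (sum(weights) <= 0) stop("all weights are zero; mean undefined", call. = FALSE)
  ang <- 2 * pi * wrap_hue(hues)
  x <- sum(weights * cos(ang))
  y <- sum(weights * sin(ang))
  if (sqrt(x^2 + y^2) < 1e-12 * sum(weights)) {
    stop("zero resultant; circular mean undefined", call. = FALSE)
  }
  wrap_hue(atan2(y, x) / (2 * pi))
}

#' Construct K uniformly spaced training bands
#'
#' Band centers sit at `shift + k/K` (k = 0..K-1); every band has
#' half-width `total_width / (2K)` so that the summed band widths equal
#' `total_width` (default 20% of the hue circle).
#'
#' @param n_classes integer K >= 2.
#' @param shift hue offset of the first band center.
#' @param total_width combined width of all bands as a fraction of the
#'   circle (default 0.2).
#' @return an object of class `hueband_set` with fields `n_classes`,
#'   `shift`, `total_width`, `centers`, `half_width`.
#' @export
make_uniform_bands <- function(n_classes, shift = 0, total_width = 0.2) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2) {
    stop("n_classes must be a single integer >= 2", call. = FALSE)
  }
  n_classes <- as.integer(n_classes)
  if (total_width <= 0 || total_width >= 1) {
    stop("total_width must lie in (0, 1)", call. = FALSE)
  }
  centers <- wrap_hue(shift + (seq_len(n_classes) - 1) / n_classes)
  structure(
    list(
      n_classes = n_classes,
      shift = wrap_hue(shift),
      total_width = total_width,
      centers = centers,
      half_width = total_width / (2 * n_classes)
    ),
    class = "hueband_set"
  )
}

#' @export
print.hueband_set <- function(x, ...) {
  cat(sprintf(
    "<hueband_set> K = %d, shift = %.4f, total width = %.2f\n  centers: %s\n",
    x$n_classes, x$shift, x$total_width,
    paste(sprintf("%.4f", x$centers), collapse = ", ")
  ))
  invisible(x)
}

#' Serialize a band set to a plain config record
#' @param bands a `hueband_set`.
#' @return a named list suitable for JSON export.
#' @export
bands_config <- function(bands) {
  stopifnot(inherits(bands, "hueband_set"))
  list(n_classes = bands$n_classes, shift = bands$shift,
       total_width = bands$total_width)
}

#' Circular band membership
#'
#' Membership uses the half-open circular interval
#' `[center - half_width, center + half_width)` so shared edges are
#' unambiguous.
#'
#' @param h hue vector.
#' @param center,half_width band geometry.
#' @return logical vector.
#' @export
band_contains <- function(h, center, half_width) {
  circ_in_interval(h, wrap_hue(center - half_width), wrap_hue(center + half_width))
}

# half-open circular interval [lo, hi); if lo == hi the interval is empty
circ_in_interval <- function(h, lo, hi) {
  h <- wrap_hue(h)
  if (lo <= hi) h >= lo & h < hi else h >= lo | h < hi
}

#' Sample hues uniformly from a band
#'
#' @param center,half_width band geometry (the band may straddle hue 0).
#' @param n number of draws.
#' @return hues in the band, wrapped to `[0, 1)`.
#' @export
sample_hue_from_band <- function(center, half_width, n = 1L) {
  wrap_hue(center + stats::runif(n, -half_width, half_width))
}

#' Sample a class's training hue from a uniform band set
#' @param bands a `hueband_set`.
#' @param class_index 0-based class label in `[0, K)`.
#' @param n number of draws.
#' @return hues drawn uniformly from the class's band.
#' @export
sample_class_hue <- function(bands, class_index, n = 1L) {
  stopifnot(class_index >= 0, class_index < bands$n_classes)
  sample_hue_from_band(bands$centers[class_index + 1L], bands$half_width, n)
}

#' Bin centers of the discretized hue spectrum
#'
#' Bin `b` of `N` (0-based) covers `[b/N, (b+1)/N)`; evaluation hues are
#' the bin centers.
#'
#' @param n_bins number of spectrum steps (default 100).
#' @return vector of `n_bins` hues.
#' @export
bin_centers <- function(n_bins = 100L) {
  (seq_len(n_bins) - 0.5) / n_bins
}

#' Bin-edge positions of the discretized spectrum
#'
#' Edge `e` (0-based) separates bin `e - 1` from bin `e`; edge 0 closes
#' the circle between the last and first bins.
#'
#' @param n_bins number of spectrum steps.
#' @return vector of `n_bins` edge hues, `e / n_bins`.
#' @export
bin_edges <- function(n_bins = 100L) {
  (seq_len(n_bins) - 1) / n_bins
}

#' Export colors as 8-bit RGB triples
#' @param rgb matrix in `[0, 1]` from [hue_to_rgb()].
#' @return integer matrix in `[0, 255]`, rounded half up.
#' @export
rgb_to_8bit <- function(rgb) {
  m <- floor(rgb * 255 + 0.5)
  storage.mode(m) <- "integer"
  m
}
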