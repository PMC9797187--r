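# Border analytics on the discretized hue circle: mode rows, transition
# detection and accumulation, circular Gaussian smoothing, circular peak
# detection, reciprocal-weighted prototypes, circular cross-correlation
# shift analysis, Fisher comparison and histogram overlap.
#
# Class labels are 0-based integers in [0, K); spectrum positions follow
# the bin convention in colorspace.R (bin b covers [b/N, (b+1)/N), edge e
# sits at e/N and edge 0 closes the circle).

#' Mode of one evaluation column
#'
#' Most frequent label in a column of per-sample predictions; ties are
#' broken to the lowest class index.
#'
#' @param column integer vector of 0-based class labels.
#' @return the modal 0-based label.
#' @export
column_mode <- function(column) {
  if (length(column) == 0L) stop("empty column has no mode", call. = FALSE)
  counts <- tabulate(column + 1L)
  which.max(counts) - 1L
}

#' Find circular transitions in a mode row
#'
#' Edge `e` (0-based; between bin `e - 1` and bin `e`) is a transition iff
#' the two labels differ; edge 0 compares the last bin against the first,
#' closing the circle.
#'
#' @param mode_row integer vector of 0-based labels, one per bin.
#' @return sorted integer vector of 0-based transition-edge indices.
#' @export
find_transitions <- function(mode_row) {
  n <- length(mode_row)
  prev <- c(mode_row[n], mode_row[-n])
  which(mode_row != prev) - 1L
}

# circular Gaussian smoothing; kernel normalized to unit mass so the
# convolution conserves the total count
circ_gauss_smooth <- function(v, sigma) {
  n <- length(v)
  off <- 0:(n - 1)
  d <- pmin(off, n - off)
  k <- exp(-d^2 / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(v) * stats::fft(k), inverse = TRUE)) / n
}

#' Accumulate border transitions over a stack of rows
#'
#' @param rows list of `classification_row` objects (see
#'   [evaluate_spectrum()]) or plain 0-based mode-row vectors, all with
#'   the same number of bins.
#' @param sigma Gaussian smoothing SD in bins (default 1.5); smoothing is
#'   circular and mass-preserving.
#' @return a `transition_count` with fields `n_bins`, `raw` (integer
#'   per-edge counts), `smoothed`, `sigma`, `n_rows`.
#' @export
accumulate_transition_counts <- function(rows, sigma = 1.5) {
  mode_rows <- lapply(rows, function(r) {
    if (inherits(r, "classification_row")) r$mode_row else as.integer(r)
  })
  n <- unique(vapply(mode_rows, length, integer(1)))
  if (length(n) != 1L) stop("rows disagree on the number of bins", call. = FALSE)
  raw <- integer(n)
  for (mr in mode_rows) {
    tr <- find_transitions(mr)
    raw[tr + 1L] <- raw[tr + 1L] + 1L
  }
  structure(
    list(n_bins = n, raw = raw, smoothed = circ_gauss_smooth(raw, sigma),
         sigma = sigma, n_rows = length(mode_rows)),
    class = "transition_count"
  )
}

#' @export
print.transition_count <- function(x, ...) {
  cat(sprintf("<transition_count> %d bins, %d rows, total transitions %d\n",
              x$n_bins, x$n_rows, sum(x$raw)))
  invisible(x)
}

# circular prominence of position i (1-based) in signal v
circ_prominence <- function(v, i) {
  n <- length(v)
  h <- v[i]
  walk <- function(step) {
    m <- Inf
    j <- i
    for (t in seq_len(n)) {
      j <- ((j - 1 + step) %% n) + 1
      if (v[j] > h) return(m)
      m <- min(m, v[j])
    }
    NA_real_ # no strictly higher value anywhere: unbounded side
  }
  mL <- walk(-1L)
  mR <- walk(+1L)
  ref <- if (is.na(mL) && is.na(mR)) min(v) else max(mL, mR, na.rm = TRUE)
  h - ref
}

#' Detect circular peaks in a transition-count signal
#'
#' Local maxima of the raw count under circular wrap, subject to a
#' minimum prominence and a minimum inter-peak separation. Plateau runs
#' count as a single candidate located at the run center.
#'
#' @param tc a `transition_count`, or a bare numeric signal.
#' @param min_separation minimum circular distance between accepted
#'   peaks, in bins (default 5).
#' @param prominence_frac minimum prominence as a fraction of the signal
#'   maximum (default 0.1).
#' @param use `"raw"` (default) or `"smoothed"` when `tc` is a
#'   `transition_count`.
#' @return a `border_estimate` with `positions` (sorted edge hues),
#'   `indices` (0-based edge indices) and `n_borders`.
#' @export
detect_peaks <- function(tc, min_separation = 5, prominence_frac = 0.1,
                         use = c("raw", "smoothed")) {
  use <- match.arg(use)
  v <- if (inherits(tc, "transition_count")) tc[[use]] else as.numeric(tc)
  n <- length(v)
  empty <- structure(list(positions = numeric(0), indices = integer(0),
                          n_borders = 0L, n_bins = n),
                     class = "border_estimate")
  if (n < 3L || diff(range(v)) == 0) return(empty)

  # circular plateau runs
  r <- rle(v)
  starts <- cumsum(c(1, utils::head(r$lengths, -1)))
  runs <- data.frame(start = starts, len = r$lengths, val = r$values)
  if (nrow(runs) > 1L && runs$val[1] == runs$val[nrow(runs)]) {
    # merge the wrap-around run
    runs$len[1] <- runs$len[1] + runs$len[nrow(runs)]
    runs$start[1] <- runs$start[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  m <- nrow(runs)
  left_val <- runs$val[c(m, seq_len(m - 1))]
  right_val <- runs$val[c(seq_len(m - 1) + 1, 1)]
  is_peak <- runs$val > left_val & runs$val > right_val
  if (!any(is_peak)) return(empty)
  cand <- runs[is_peak, , drop = FALSE]
  # run-center position (circular)
  cand_idx <- ((cand$start - 1 + (cand$len - 1) %/% 2) %% n) + 1

  prom <- vapply(cand_idx, function(i) circ_prominence(v, i), numeric(1))
  keep <- prom >= prominence_frac * max(v)
  cand_idx <- cand_idx[keep]
  heights <- v[cand_idx]
  prom <- prom[keep]
  if (length(cand_idx) == 0L) return(empty)

  # greedy acceptance by height (ties: prominence, then index), enforcing
  # a minimum circular separation
  ord <- order(-heights, -prom, cand_idx)
  accepted <- integer(0)
  for (i in ord) {
    idx <- cand_idx[i]
    if (length(accepted) == 0L) {
      accepted <- idx
    } else {
      dd <- abs(accepted - idx)
      dd <- pmin(dd, n - dd)
      if (all(dd >= min_separation)) accepted <- c(accepted, idx)
    }
  }
  accepted <- sort(accepted)
  structure(
    list(positions = (accepted - 1) / n, indices = as.integer(accepted - 1L),
         n_borders = length(accepted), n_bins = n),
    class = "border_estimate"
  )
}

#' @export
print.border_estimate <- function(x, ...) {
  cat(sprintf("<border_estimate> %d borders: %s\n", x$n_borders,
              paste(sprintf("%.3f", x$positions), collapse = ", ")))
  invisible(x)
}

#' Reciprocal-weighted category prototypes
#'
#' For each category interval between consecutive borders, the prototype
#' is the circular mean of member-bin hues weighted by the reciprocal of
#' the raw transition count, `1 / (raw + 1)` (the +1 avoids division by
#' zero at untraversed bins). Bins belong to the category whose circular
#' interval `[left, right)` contains their center.
#'
#' @param borders a `border_estimate` with at least 2 borders.
#' @param tc the `transition_count` the borders were detected in.
#' @return a data frame with columns `left`, `right`, `prototype`,
#'   `r`, `g`, `b` (one row per category).
#' @export
compute_prototypes <- function(borders, tc) {
  pos <- borders$positions
  if (length(pos) < 2L) stop("need at least 2 borders", call. = FALSE)
  n <- tc$n_bins
  centers <- bin_centers(n)
  w <- 1 / (tc$raw + 1)
  k <- length(pos)
  out <- data.frame(left = pos, right = pos[c(2:k, 1)], prototype = NA_real_)
  for (i in seq_len(k)) {
    member <- circ_in_interval(centers, out$left[i], out$right[i])
    if (!any(member)) stop("empty category interval", call. = FALSE)
    out$prototype[i] <- circular_weighted_mean(centers[member], w[member])
  }
  rgb <- hue_to_rgb(out$prototype)
  out$r <- rgb[, 1]; out$g <- rgb[, 2]; out$b <- rgb[, 3]
  out
}

#' Map a mode row to unit-circle coordinate signals
#'
#' Each bin's 0-based label is replaced by its training-band center hue,
#' then mapped to `(cos 2*pi*h, sin 2*pi*h)`, preserving the circular
#' topology of hue for cross-correlation.
#'
#' @param mode_row 0-based labels.
#' @param bands the `hueband_set` the row was trained on.
#' @return a list with numeric signals `x` and `y`.
#' @export
row_to_unit_circle <- function(mode_row, bands) {
  if (any(mode_row < 0L) || any(mode_row >= bands$n_classes)) {
    stop("labels out of range for band set", call. = FALSE)
  }
  h <- bands$centers[mode_row + 1L]
  ang <- 2 * pi * h
  list(x = cos(ang), y = sin(ang))
}

# fold a raw lag (0 .. n-1) into (-P/2, P/2]
fold_shift <- function(lag, period) {
  t <- lag %% period
  ifelse(t > period / 2, t - period, t)
}

# full circular cross-correlation of two complex signals via FFT:
# C[s + 1] = sum_b Re( Conj(zA[b]) * zB[b + s] )
cross_corr_all_lags <- function(fa, fb) {
  n <- length(fa)
  Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / n
}

#' Optimal circular shift between two mode rows
#'
#' Both rows are mapped to unit-circle coordinates, the summed x/y
#' cross-correlation is evaluated at every circular lag, and the
#' maximizing lag is folded into `(-P/2, P/2]` with
#' `P = round(n_bins / K)`; the fold uses the true (fractional) class
#' period `n_bins / K` before rounding, which keeps alignment residues
#' exact (see the source note on aliasing). Ties are broken to the
#' smallest absolute folded shift, then negative first. Positive shift
#' means row B lags row A (B equals A rotated forward): a row against
#' itself rotated by 10 bins at `n_bins = 100`, K = 7 reports -4.
#'
#' @param rowA,rowB `classification_row` objects or 0-based mode-row
#'   vectors of equal length.
#' @param bandsA,bandsB band sets for the rows (taken from the rows'
#'   provenance when omitted).
#' @return signed integer shift in bins, in `(-P/2, P/2]`.
#' @export
optimal_circular_shift <- function(rowA, rowB, bandsA = NULL, bandsB = NULL) {
  if (inherits(rowA, "classification_row")) {
    if (is.null(bandsA)) bandsA <- rowA$bands
    rowA <- rowA$mode_row
  }
  if (inherits(rowB, "classification_row")) {
    if (is.null(bandsB)) bandsB <- rowB$bands
    rowB <- rowB$mode_row
  }
  if (length(rowA) != length(rowB)) stop("rows differ in length", call. = FALSE)
  if (bandsA$n_classes != bandsB$n_classes) {
    stop("rows have incompatible class counts", call. = FALSE)
  }
  n <- length(rowA)
  ca <- row_to_unit_circle(rowA, bandsA)
  cb <- row_to_unit_circle(rowB, bandsB)
  cc <- cross_corr_all_lags(stats::fft(complex(real = ca$x, imaginary = ca$y)),
                            stats::fft(complex(real = cb$x, imaginary = cb$y)))
  pick_best_shift(cc, n, bandsA$n_classes)
}

# global argmax over all circular lags, folded into (-P/2, P/2].
# Folding uses the true class period n/K (fractional) before rounding:
# the row structure repeats every n/K bins, and folding by the rounded
# integer period instead would alias lags several sub-periods away from
# the origin (e.g. lag 94 at n = 100, K = 7 is alignment residue -6, but
# 94 mod 14 would report -4). The rounded result is snapped back into
# the integer support. Ties: smallest |shift|, negative before positive.
pick_best_shift <- function(cc, n_bins, K) {
  period <- round(n_bins / K)
  true_period <- n_bins / K
  tol <- 1e-9 * max(1, abs(max(cc)))
  cand <- which(cc >= max(cc) - tol) - 1L
  f <- cand %% true_period
  f <- ifelse(f > true_period / 2, f - true_period, f)
  s <- fold_shift(round(f), period)
  ord <- order(abs(s), s)
  as.integer(s[ord[1]])
}

#' Distribution of pairwise optimal shifts over a row stack
#'
#' Each unordered pair of rows contributes one optimal circular shift.
#' Signed shifts support plotting; absolute shifts feed the count tables
#' used for testing.
#'
#' @param rows list of `classification_row` objects sharing `n_bins` and
#'   `K` (band shifts may differ).
#' @return a `shift_histogram` with `period`, `signed_support`,
#'   `signed_counts`, `abs_support`, `abs_counts`, `shifts` (the raw
#'   pairwise values).
#' @export
shift_distribution <- function(rows) {
  if (length(rows) < 2L) stop("need at least 2 rows", call. = FALSE)
  n <- length(rows[[1]]$mode_row)
  K <- rows[[1]]$bands$n_classes
  period <- round(n / K)
  fts <- lapply(rows, function(r) {
    cc <- row_to_unit_circle(r$mode_row, r$bands)
    stats::fft(complex(real = cc$x, imaginary = cc$y))
  })
  m <- length(rows)
  shifts <- integer(m * (m - 1) / 2)
  k <- 0L
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      k <- k + 1L
      shifts[k] <- pick_best_shift(cross_corr_all_lags(fts[[i]], fts[[j]]), n, K)
    }
  }
  signed_support <- seq.int(-floor((period - 1) / 2), floor(period / 2))
  signed_counts <- vapply(signed_support, function(s) sum(shifts == s), integer(1))
  abs_support <- seq.int(0, floor(period / 2))
  abs_counts <- vapply(abs_support, function(s) sum(abs(shifts) == s), integer(1))
  structure(
    list(period = period, signed_support = signed_support,
         signed_counts = signed_counts, abs_support = abs_support,
         abs_counts = abs_counts, shifts = shifts),
    class = "shift_histogram"
  )
}

#' @export
print.shift_histogram <- function(x, ...) {
  cat(sprintf("<shift_histogram> period %d, %d pairs, %.1f%% with |shift| <= 2\n",
              x$period, length(x$shifts), 100 * mean(abs(x$shifts) <= 2)))
  invisible(x)
}

#' Fisher's exact test on shift-count tables
#'
#' Compares two or three per-shift count distributions (an r x 2 or r x 3
#' contingency table). Totals up to `enumeration_cap` are tested exactly;
#' larger tables use a Monte-Carlo p-value with its standard error
#' attached.
#'
#' @param countsA,countsB,countsC nonnegative integer vectors over the
#'   same shift support (`countsC` optional).
#' @param enumeration_cap largest table total tested exactly (default 200).
#' @param n_mc Monte-Carlo replicates above the cap (default 1e5).
#' @return a list with `p_value`, `method` (`"exact"` or `"monte-carlo"`)
#'   and `se` (NA for exact).
#' @export
fisher_exact_table <- function(countsA, countsB, countsC = NULL,
                               enumeration_cap = 200, n_mc = 1e5) {
  cols <- list(countsA, countsB)
  if (!is.null(countsC)) cols <- c(cols, list(countsC))
  lens <- vapply(cols, length, integer(1))
  if (length(unique(lens)) != 1L) stop("count vectors differ in support", call. = FALSE)
  tab <- do.call(cbind, cols)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  storage.mode(tab) <- "integer"
  tab <- tab[rowSums(tab) > 0, , drop = FALSE] # empty rows carry no information
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(p_value = 1, method = "degenerate", se = NA_real_))
  }
  if (sum(tab) <= enumeration_cap) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    list(p_value = min(p, 1), method = "exact", se = NA_real_)
  } else {
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
    list(p_value = min(p, 1), method = "monte-carlo",
         se = sqrt(p * (1 - p) / n_mc))
  }
}

#' Percentage overlap of two count distributions
#'
#' Histogram intersection: both count vectors are normalized to
#' frequencies and the bin-wise minima summed.
#'
#' @param histA,histB nonnegative count vectors over the same support.
#' @return overlap in percent (0-100).
#' @export
distribution_overlap <- function(histA, histB) {
  if (length(histA) != length(histB) || length(histA) == 0L) {
    stop("histograms must share a non-empty support", call. = FALSE)
  }
  if (sum(histA) <= 0 || sum(histB) <= 0) {
    stop("empty histogram", call. = FALSE)
  }
  100 * sum(pmin(histA / sum(histA), histB / sum(histB)))
}
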