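# Seed fan-out and scoped RNG state. A single run seed is hashed with a
# small set of integer keys so that sub-experiments (rows, generations,
# members) are independently reproducible without sharing streams.

#' Derive a child seed from a parent seed and integer keys
#'
#' Multiplicative hashing modulo the Mersenne prime 2^31 - 1 keeps every
#' derived seed a valid 32-bit R seed.
#'
#' @param seed parent seed (integer).
#' @param ... integer keys identifying the sub-computation.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647
  h <- 17
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% m)) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so calling code's RNG stream is
#' untouched.
#'
#' @param seed integer seed; `NULL` leaves the current stream in place.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
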