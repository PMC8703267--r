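# Sobol low-discrepancy sequence, Gray-code construction with Joe-Kuo
# direction numbers (primitive polynomials and initial values for the first
# 16 dimensions; enough for the 14-column Saltelli base design used here).
# Hand-rolled because no installed package provides a quasi-random generator.

# primitive polynomial encodings (leading and trailing coefficient included)
.sobol_poly <- c(
  1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L, 67L, 91L, 97L
)

# initial direction integers m_j per dimension (row d, j = 1..degree)
.sobol_minit <- list(
  c(1L),
  c(1L),
  c(1L, 3L),
  c(1L, 3L, 1L),
  c(1L, 1L, 1L),
  c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L),
  c(1L, 1L, 5L, 5L, 17L),
  c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L),
  c(1L, 1L, 5L, 1L, 1L),
  c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L),
  c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L),
  c(1L, 3L, 1L, 13L, 27L, 49L)
)

.sobol_maxbit <- 31L

# direction integers V[1..nbits] for one dimension, scaled to 2^31
sobol_directions <- function(dim, nbits) {
  stopifnot(dim >= 1L, dim <= length(.sobol_poly))
  v <- integer(nbits)
  if (dim == 1L) {
    for (j in seq_len(nbits)) v[j] <- bitwShiftL(1L, .sobol_maxbit - j)
    return(v)
  }
  poly <- .sobol_poly[dim]
  s <- floor(log2(poly))
  a <- bitwShiftR(poly - bitwShiftL(1L, s) - 1L, 1L)
  m <- .sobol_minit[[dim]]
  for (j in seq_len(min(s, nbits))) {
    v[j] <- bitwShiftL(m[j], .sobol_maxbit - j)
  }
  if (nbits > s) {
    for (j in (s + 1L):nbits) {
      vj <- bitwXor(v[j - s], bitwShiftR(v[j - s], s))
      if (s > 1L) {
        for (k in 1L:(s - 1L)) {
          if (bitwAnd(bitwShiftR(a, s - 1L - k), 1L) == 1L) {
            vj <- bitwXor(vj, v[j - k])
          }
        }
      }
      v[j] <- vj
    }
  }
  v
}

#' Sobol low-discrepancy points in the unit hypercube
#'
#' Generates `n` points of the `d`-dimensional Sobol sequence (Gray-code
#' order, Joe-Kuo direction numbers, up to 16 dimensions). The initial
#' all-zero point of the sequence is skipped so the first row is (0.5, ...,
#' 0.5). An optional seeded random digital shift (bitwise XOR of a fixed
#' random integer per dimension) decorrelates replicate designs while
#' preserving the sequence's equidistribution.
#'
#' @param n Number of points.
#' @param d Dimension (1..16).
#' @param seed Optional integer seed for the digital shift; `NULL` (default)
#'   gives the unshifted sequence.
#' @return An `n x d` matrix with entries in (0, 1).
#' @export
sobol_points <- function(n, d, seed = NULL) {
  stopifnot(n >= 1L, d >= 1L, d <= length(.sobol_poly))
  nbits <- max(1L, ceiling(log2(n + 2)))
  nbits <- min(nbits, 30L)
  x <- matrix(0L, nrow = n, ncol = d)
  for (dd in seq_len(d)) {
    v <- sobol_directions(dd, nbits)
    acc <- 0L
    # skip index 0 (the all-zero point): start the Gray-code walk at i = 1
    for (i in seq_len(n)) {
      # lowest zero bit of (i - 1), 1-indexed
      c <- 1L
      val <- i - 1L
      while (bitwAnd(val, 1L) == 1L) {
        val <- bitwShiftR(val, 1L)
        c <- c + 1L
      }
      acc <- bitwXor(acc, v[c])
      x[i, dd] <- acc
    }
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    shift <- as.integer(floor(stats::runif(d) * 2^.sobol_maxbit))
    for (dd in seq_len(d)) x[, dd] <- bitwXor(x[, dd], shift[dd])
  }
  x / 2^.sobol_maxbit
}
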