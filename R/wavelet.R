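# Periodized orthogonal discrete wavelet transform with the Daubechies-8
# scaling filter (8 vanishing moments, 16 taps).  Coefficients are the
# standard orthonormal values (sum = sqrt(2), unit energy, shift-2
# orthogonality ~ 1e-16), frozen from spectral factorization of the
# Daubechies half-band polynomial.

DB8_LO <- c(
  5.44158422431039665e-02, 3.12871590914299780e-01,
  6.75630736297289203e-01, 5.85354683654206176e-01,
  -1.58291052563480777e-02, -2.84015542961546574e-01,
  4.72484573912953360e-04, 1.28747426620478750e-01,
  -1.73693010018078076e-02, -4.40882539307946159e-02,
  1.39810279173982633e-02, 8.74609404740574539e-03,
  -4.87035299345156027e-03, -3.91740373376948242e-04,
  6.75449406450568464e-04, -1.17476784124769345e-04
)
# quadrature mirror high-pass: g[m] = (-1)^m h[L-1-m]
DB8_HI <- rev(DB8_LO) * rep_len(c(1, -1), length(DB8_LO))

# One periodized analysis step.  Odd-length inputs are padded by repeating
# the last sample (the pad is dropped again on reconstruction).
dwt_step <- function(x) {
  n <- length(x)
  padded <- n %% 2L == 1L
  if (padded) x <- c(x, x[n])
  np <- length(x)
  half <- np %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(DB8_LO)) {
    idx <- (k2 + (m - 1L)) %% np + 1L
    a <- a + DB8_LO[m] * x[idx]
    d <- d + DB8_HI[m] * x[idx]
  }
  list(a = a, d = d, n = n)
}

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
idwt_step <- function(a, d, n) {
  half <- length(a)
  np <- 2L * half
  x <- numeric(np)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(DB8_LO)) {
    idx <- (k2 + (m - 1L)) %% np + 1L
    acc <- DB8_LO[m] * a + DB8_HI[m] * d
    # scatter-add; idx values are unique within one m
    x[idx] <- x[idx] + acc
  }
  x[seq_len(n)]
}

#' Multilevel Daubechies-8 decomposition of a 1D signal
#'
#' @param x numeric vector, length >= 16 (the filter support).
#' @param levels number of decomposition levels.
#' @return list with `approx` (coarsest approximation) and `details`
#'   (list of detail bands, finest first) plus the per-level lengths.
#' @keywords internal
dwt_multilevel <- function(x, levels) {
  if (length(x) < length(DB8_LO)) {
    stop("signal shorter than the Daubechies-8 filter support (16)")
  }
  max_levels <- max(1L, floor(log2(length(x) / (length(DB8_LO) - 1))))
  if (levels > max_levels) {
    stop(sprintf("drop_levels %d exceeds decomposition depth %d for length %d",
                 levels, max_levels, length(x)))
  }
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(cur)
    details[[l]] <- s$d
    lens[l] <- s$n
    cur <- s$a
  }
  list(approx = cur, details = details, lens = lens)
}

idwt_multilevel <- function(dec) {
  cur <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    cur <- idwt_step(cur, dec$details[[l]], dec$lens[l])
  }
  cur
}

# Denoise one row: decompose `drop_levels` levels, zero all detail bands,
# reconstruct.  Equivalent to zeroing the finest drop_levels bands of any
# deeper decomposition.
wavelet_denoise_row <- function(x, drop_levels) {
  if (drop_levels == 0L) {
    dec <- dwt_multilevel(x, 1L)
    return(idwt_multilevel(dec))
  }
  dec <- dwt_multilevel(x, drop_levels)
  dec$details <- lapply(dec$details, function(d) numeric(length(d)))
  idwt_multilevel(dec)
}
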