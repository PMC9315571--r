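# Independent oracles used across the suite. These deliberately re-derive
# quantities with different algorithms than the package implementation.

# Random test cube with the standard 18-channel 640-810 nm grid, plus a
# rising baseline so background target values are positive.
make_test_cube <- function(rows = 5, cols = 5, seed = 1,
                           wavelengths = seq(640, 810, by = 10)) {
  set.seed(seed)
  n <- length(wavelengths)
  base <- 50 + (wavelengths - 640) * 0.5
  arr <- array(stats::runif(rows * cols * n, 0, 10), c(rows, cols, n))
  for (k in seq_len(n)) arr[, , k] <- arr[, , k] + base[k]
  spectral_cube(arr, wavelengths, name = "test")
}

# Point-in-polygon by explicit horizontal-ray crossing count, written as a
# scalar double loop (distinct from the package's vectorized xor form).
pip_oracle <- function(py, px, V) {
  n <- nrow(V)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- V[i, 1L]; x1 <- V[i, 2L]
    y2 <- V[j, 1L]; x2 <- V[j, 2L]
    if ((y1 <= py && py < y2) || (y2 <= py && py < y1)) {
      xi <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xi) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(n1+n2, n1) group labelings (no ties assumed), mirroring the standard
# two-sided doubling convention.
enum_rank_sum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(N, n1)
  ranks <- seq_len(N)
  u_all <- apply(labelings, 2L, function(idx) sum(ranks[idx])) -
    n1 * (n1 + 1) / 2
  if (u_obs > n1 * n2 / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Magnitude of the DFT bin at frequency f for a buffer (exact bin match).
bin_magnitude <- function(display, f) {
  i <- which.min(abs(display$frequencies_hz - f))
  stopifnot(abs(display$frequencies_hz[i] - f) < 1e-6)
  display$magnitudes[i]
}
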