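# Brute-force references kept deliberately independent of the package's
# vectorized implementation paths.

# Per-placement double loop: extract every I x J pattern and encode it with
# the scalar texture_unit(). Returns a named count vector (names = k).
naive_histogram <- function(img, I, J) {
  M <- nrow(img); N <- ncol(img)
  units <- numeric((M - I + 1) * (N - J + 1))
  pos <- 0L
  for (r in seq_len(M - I + 1)) {
    for (cc in seq_len(N - J + 1)) {
      pos <- pos + 1L
      units[pos] <- texture_unit(img[r:(r + I - 1), cc:(cc + J - 1),
                                     drop = FALSE])
    }
  }
  table(units)
}

# Brute-force Otsu: maximize between-class variance over t = 0..254 by
# explicit group means, smallest argmax.
naive_otsu <- function(img) {
  v <- round(as.vector(img))
  best_t <- 0L; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

random_binary <- function(M, N, p = 0.5) {
  matrix(as.numeric(runif(M * N) < p), M, N)
}

# Sparse spectra as plain named vectors, for readable comparisons.
spectrum_vec <- function(s) stats::setNames(s$p, format(s$k, scientific = FALSE, trim = TRUE))
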