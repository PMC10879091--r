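# Independent oracles used across the suite. Deliberately naive: they share
# no code with the implementation under test.

# One-sided magnitude spectrum of x zero-padded to pad_len, computed as a
# direct O(n^2) discrete Fourier sum (no FFT).
brute_dft_onesided <- function(x, pad_len) {
  n <- length(x)
  k <- 0:(pad_len %/% 2L)
  t <- 0:(n - 1L)
  ang <- -2 * pi * outer(k, t) / pad_len
  re <- as.vector(cos(ang) %*% x)
  im <- as.vector(sin(ang) %*% x)
  sqrt(re^2 + im^2)
}

# Textbook two-pass Pearson correlation (absolute value).
cor_twopass_abs <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  abs(num) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Build a centered channel with an exact correlation rho to a reference
# channel, using an orthonormal centered basis pair.
make_pair_with_cor <- function(n, rho, seed = 1) {
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n)
  a <- a - mean(a)
  b <- b - mean(b)
  b <- b - sum(a * b) / sum(a * a) * a   # orthogonalize
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  rbind(a, rho * a + sqrt(1 - rho^2) * b)
}

# Minimal PNG header inspection: width/height from IHDR (big-endian).
png_dims <- function(path) {
  raw <- readBin(path, "raw", 33L)
  stopifnot(identical(as.integer(raw[1:8]),
                      c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
  be32 <- function(b) sum(as.integer(b) * 256^(3:0))
  c(height = be32(raw[21:24]), width = be32(raw[17:20]))
}
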