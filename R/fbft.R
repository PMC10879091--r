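# Forward-Backward Fourier Transform (FBFT).
#
# For every time index u the signal is split into the prefix x[0..u] and
# the suffix x[u..n-1] (0-based; sample u belongs to both). Each subarray
# is zero-padded to a common length, Fourier transformed, and the
# time-frequency magnitude at (f, u) is the element-wise MINIMUM of the
# two one-sided spectra. A frequency survives at time u only if it is
# present both before and after u, which pins oscillatory components to
# their activity interval far more sharply than a plain FFT.

# one-sided |FFT| of x zero-padded to pad_len
onesided_padded_mag <- function(x, pad_len) {
  buf <- numeric(pad_len)
  buf[seq_along(x)] <- x
  Mod(stats::fft(buf))[seq_len(pad_len %/% 2L + 1L)]
}

check_pad <- function(pad_len, n) {
  if (!is.numeric(pad_len) || length(pad_len) != 1L || pad_len < n)
    stop_fbft(sprintf("'pad_len' (%s) must be >= n_samples (%d): zero padding must extend the signal",
                      format(pad_len), n), "fbft_parameter_error")
  as.integer(pad_len)
}

# evaluated time indices (0-based): every `stride`-th u, always keeping n-1
u_grid <- function(n, stride) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1L)
    stop_fbft("'stride' must be >= 1", "fbft_parameter_error")
  unique(c(seq.int(0L, n - 1L, by = as.integer(stride)), n - 1L))
}

#' Cumulative prefix spectra
#'
#' For each evaluated time index `u` (every `stride`-th index, the last
#' index always included), the one-sided magnitude spectrum of the prefix
#' `x[0..u]` (0-based, inclusive) zero-padded to `pad_len`. Columns are the
#' forward half of the FBFT.
#'
#' @param x numeric vector, single-channel samples.
#' @param pad_len FFT length; must be `>= length(x)` so the padding extends
#'   the signal.
#' @param stride evaluation step along the time axis (default 1).
#' @return numeric matrix `(pad_len %/% 2 + 1) x n_evaluated`, with the
#'   evaluated 0-based indices attached as attribute `"u"`.
#' @export
prefix_spectra <- function(x, pad_len, stride = 1L) {
  n <- length(x)
  pad_len <- check_pad(pad_len, n)
  us <- u_grid(n, stride)
  out <- matrix(0, nrow = pad_len %/% 2L + 1L, ncol = length(us))
  for (j in seq_along(us))
    out[, j] <- onesided_padded_mag(x[seq_len(us[j] + 1L)], pad_len)
  attr(out, "u") <- us
  out
}

#' Cumulative suffix spectra
#'
#' The backward half of the FBFT: the column for time index `u` is the
#' one-sided magnitude spectrum of the suffix `x[u..n-1]` (0-based,
#' inclusive) zero-padded to `pad_len`. With this alignment column `u`
#' pairs prefix `x[0..u]` with suffix `x[u..n-1]`; sample `u` belongs to
#' both subarrays.
#'
#' @inheritParams prefix_spectra
#' @return as [prefix_spectra()].
#' @export
suffix_spectra <- function(x, pad_len, stride = 1L) {
  n <- length(x)
  pad_len <- check_pad(pad_len, n)
  us <- u_grid(n, stride)
  out <- matrix(0, nrow = pad_len %/% 2L + 1L, ncol = length(us))
  for (j in seq_along(us))
    out[, j] <- onesided_padded_mag(x[(us[j] + 1L):n], pad_len)
  attr(out, "u") <- us
  out
}

#' Forward-Backward Fourier Transform
#'
#' Computes the FBFT time-frequency map of a single-channel signal:
#' `magnitude[f, u] = min(|FFT_pad(x[0..u])|[f], |FFT_pad(x[u..n-1])|[f])`
#' on a common zero-padded frequency grid, with `freqs[f] = f * fs /
#' pad_len` and `times[u] = u / fs`. The minimum suppresses any frequency
#' that is not active on both sides of `u`, including spurious harmonics
#' introduced by truncation, so components appear only over their true
#' activity intervals.
#'
#' Raw prefix/suffix magnitudes grow with subarray length; `normalize =
#' TRUE` divides each spectrum by its subarray length before the minimum
#' (an opt-in for visualization — the default follows the raw definition).
#'
#' @param x numeric vector or a single-channel `fbft_signal`.
#' @param fs sampling rate in Hz (taken from the signal if one is given).
#' @param pad_len common FFT length, `>= n`; `"auto"` (default) uses the
#'   smallest power of two `>= 2 * n`, giving all subarrays one frequency
#'   grid and an efficient FFT size.
#' @param stride evaluate every `stride`-th time index (default 1; the last
#'   index is always evaluated). Thinning the grid is a pure restriction:
#'   the computed columns equal the stride-1 columns at the same indices.
#' @param normalize divide each subarray spectrum by its length before the
#'   minimum (default `FALSE`).
#' @return an `fbft_tf_map`; `meta` records `transform = "fbft"`, `fs`,
#'   `pad_len`, `stride`, `normalize`, and the evaluated indices `u`.
#' @examples
#' s <- preset_signal("fig4")
#' tf <- fbft(s, stride = 4)
#' ridge_frequencies(tf, c(0, 1))  # ~10 Hz
#' @export
fbft <- function(x, fs = NULL, pad_len = "auto", stride = 1L,
                 normalize = FALSE) {
  if (inherits(x, "fbft_signal")) {
    if (n_channels(x) != 1L)
      stop_fbft("fbft() takes a single channel; use select_signal_channels()",
                "fbft_parameter_error")
    fs <- x$fs
    x <- as.numeric(x$samples[1L, ])
  }
  if (is.null(fs)) stop_fbft("'fs' is required for a plain vector", "fbft_parameter_error")
  n <- length(x)
  if (n < 2L) stop_fbft("fbft needs at least 2 samples", "fbft_parameter_error")
  if (identical(pad_len, "auto")) pad_len <- next_pow2(2L * n)
  pad_len <- check_pad(pad_len, n)
  pre <- prefix_spectra(x, pad_len, stride)
  suf <- suffix_spectra(x, pad_len, stride)
  us <- attr(pre, "u")
  if (normalize) {
    pre <- sweep(pre, 2L, us + 1, "/")
    suf <- sweep(suf, 2L, n - us, "/")
  }
  mag <- pmin(pre, suf)
  attr(mag, "u") <- NULL
  tf_map(mag,
         freqs = (seq_len(pad_len %/% 2L + 1L) - 1L) * fs / pad_len,
         times = us / fs,
         meta = list(transform = "fbft", fs = fs, pad_len = pad_len,
                     stride = as.integer(stride), normalize = normalize,
                     u = us))
}

#' Literal FBFT reference implementation
#'
#' A direct, unvectorized transcription of the defining procedure, kept as
#' the oracle the production path is verified against: iterate `u` over
#' the signal, FFT each zero-padded prefix slice into a list `M`; iterate
#' again, FFT each zero-padded suffix slice `x[-u-1:]` into a list `M1`;
#' reverse `M1`; take the element-wise minimum of the magnitudes. Always
#' stride 1, raw (unnormalized) magnitudes.
#'
#' @inheritParams fbft
#' @return an `fbft_tf_map` with `meta$transform = "fbft_reference"`.
#' @export
fbft_reference <- function(x, fs = NULL, pad_len = "auto") {
  if (inherits(x, "fbft_signal")) {
    fs <- x$fs
    x <- as.numeric(x$samples[1L, ])
  }
  if (is.null(fs)) stop_fbft("'fs' is required for a plain vector", "fbft_parameter_error")
  n <- length(x)
  if (n < 2L) stop_fbft("fbft needs at least 2 samples", "fbft_parameter_error")
  if (identical(pad_len, "auto")) pad_len <- next_pow2(2L * n)
  pad_len <- check_pad(pad_len, n)
  M <- vector("list", n)
  for (u in 0:(n - 1L)) {                 # slice from the beginning to u+1
    H <- x[1:(u + 1L)]
    M[[u + 1L]] <- onesided_padded_mag(H, pad_len)
  }
  M1 <- vector("list", n)
  for (u in 0:(n - 1L)) {                 # slice from -u-1 to the end
    H1 <- x[(n - u):n]
    M1[[u + 1L]] <- onesided_padded_mag(H1, pad_len)
  }
  M1 <- rev(M1)
  mag <- matrix(0, nrow = pad_len %/% 2L + 1L, ncol = n)
  for (u in seq_len(n))
    mag[, u] <- pmin(M[[u]], M1[[u]])
  tf_map(mag,
         freqs = (seq_len(pad_len %/% 2L + 1L) - 1L) * fs / pad_len,
         times = (seq_len(n) - 1L) / fs,
         meta = list(transform = "fbft_reference", fs = fs, pad_len = pad_len,
                     stride = 1L, normalize = FALSE, u = 0:(n - 1L)))
}
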