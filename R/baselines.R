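# Comparison transforms. These are standard textbook methods (the package's
# contribution is the FBFT, not these); no signal-processing package is
# available in the supported dependency set, so minimal direct
# implementations on top of stats::fft are provided, all emitting the same
# fbft_tf_map container so maps are directly comparable.

#' Baseline transform specification
#'
#' @param method one of `"stft"`, `"cwt"`, `"dwt"`, `"power_spectrum"`.
#' @param window_n STFT window length in samples (default 256, Hann
#'   window).
#' @param hop_n STFT hop in samples (default `window_n %/% 4`).
#' @param n_scales number of CWT scales, log-spaced in frequency
#'   (default 64).
#' @param freq_range CWT frequency range in Hz, default `c(1, fs/2)`
#'   resolved at transform time.
#' @param omega0 Morlet center frequency parameter (default 6).
#' @param levels DWT decomposition depth; default `min(6, floor(log2(n)))`
#'   resolved at transform time; must satisfy `levels <= log2(n)`.
#' @return an object of class `fbft_baseline_spec`.
#' @export
baseline_spec <- function(method = c("stft", "cwt", "dwt", "power_spectrum"),
                          window_n = 256L, hop_n = NULL,
                          n_scales = 64L, freq_range = NULL, omega0 = 6,
                          levels = NULL) {
  method <- match.arg(method)
  if (window_n < 2L) stop_fbft("'window_n' must be >= 2", "fbft_parameter_error")
  hop_n <- hop_n %||% max(1L, window_n %/% 4L)
  if (hop_n < 1L) stop_fbft("'hop_n' must be >= 1", "fbft_parameter_error")
  if (n_scales < 2L) stop_fbft("'n_scales' must be >= 2", "fbft_parameter_error")
  structure(list(method = method, window_n = as.integer(window_n),
                 hop_n = as.integer(hop_n), n_scales = as.integer(n_scales),
                 freq_range = freq_range, omega0 = omega0, levels = levels),
            class = "fbft_baseline_spec")
}

#' Baseline time-frequency transforms
#'
#' Computes a comparison map with the named method on the same axes
#' conventions as [fbft()]:
#' * `stft` — Hann-windowed short-time Fourier magnitude spectrogram.
#' * `cwt` — Morlet continuous-wavelet scalogram on a log-spaced frequency
#'   grid (FFT-based convolution).
#' * `dwt` — Haar discrete-wavelet band map rendered as a
#'   piecewise-constant time-by-band image, one row per decomposition
#'   level (a dyadic filter bank is not naturally a dense TF grid).
#' * `power_spectrum` — one-sided periodogram, a single-time-column map,
#'   scaled so that `sum(psd) * delta_f` equals the mean square of the
#'   signal.
#'
#' @param x numeric vector or single-channel `fbft_signal`.
#' @param fs sampling rate in Hz (taken from the signal if one is given).
#' @param spec an [baseline_spec()].
#' @return an `fbft_tf_map`.
#' @export
baseline_tf <- function(x, fs = NULL, spec = baseline_spec("stft")) {
  stopifnot(inherits(spec, "fbft_baseline_spec"))
  if (inherits(x, "fbft_signal")) {
    if (n_channels(x) != 1L)
      stop_fbft("baseline_tf() takes a single channel", "fbft_parameter_error")
    fs <- x$fs
    x <- as.numeric(x$samples[1L, ])
  }
  if (is.null(fs)) stop_fbft("'fs' is required for a plain vector", "fbft_parameter_error")
  switch(spec$method,
         stft = tf_stft(x, fs, spec),
         cwt = tf_cwt(x, fs, spec),
         dwt = tf_dwt(x, fs, spec),
         power_spectrum = tf_power_spectrum(x, fs))
}

tf_stft <- function(x, fs, spec) {
  n <- length(x)
  wl <- spec$window_n
  if (wl > n)
    stop_fbft("STFT window longer than the signal", "fbft_parameter_error")
  hop <- spec$hop_n
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1L) / (wl - 1L))  # Hann
  starts <- seq.int(1L, n - wl + 1L, by = hop)
  nb <- wl %/% 2L + 1L
  mag <- matrix(0, nrow = nb, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + wl - 1L)] * win
    mag[, j] <- Mod(stats::fft(seg))[seq_len(nb)]
  }
  tf_map(mag,
         freqs = (seq_len(nb) - 1L) * fs / wl,
         times = (starts - 1L + (wl - 1L) / 2) / fs,   # frame centers
         meta = list(transform = "stft", fs = fs, window_n = wl, hop_n = hop))
}

tf_cwt <- function(x, fs, spec) {
  n <- length(x)
  fr <- spec$freq_range %||% c(1, fs / 2)
  if (fr[1] <= 0 || fr[2] > fs / 2 || fr[1] >= fr[2])
    stop_fbft("'freq_range' must satisfy 0 < fmin < fmax <= fs/2",
              "fbft_parameter_error")
  freqs <- exp(seq(log(fr[1]), log(fr[2]), length.out = spec$n_scales))
  w0 <- spec$omega0
  scales <- w0 * fs / (2 * pi * freqs)    # scale s such that f = w0 / (2 pi s/fs)
  X <- stats::fft(x)
  wk <- 2 * pi * (seq_len(n) - 1L) / n    # angular frequency grid (cycles/sample)
  wk[wk > pi] <- wk[wk > pi] - 2 * pi
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-(s * wk - w0)^2 / 2) * (wk > 0)
    mag[i, ] <- Mod(stats::fft(X * psi, inverse = TRUE)) / n
  }
  tf_map(mag[order(freqs), , drop = FALSE],
         freqs = sort(freqs),
         times = (seq_len(n) - 1L) / fs,
         meta = list(transform = "cwt", fs = fs, omega0 = w0,
                     n_scales = spec$n_scales))
}

# one level of the Haar analysis filter bank (periodic, orthonormal)
haar_step <- function(v) {
  m <- length(v) %/% 2L
  even <- v[2L * seq_len(m) - 1L]
  odd <- v[2L * seq_len(m)]
  list(approx = (even + odd) / sqrt(2), detail = (even - odd) / sqrt(2))
}

tf_dwt <- function(x, fs, spec) {
  n <- length(x)
  max_lev <- floor(log2(n))
  lev <- spec$levels %||% min(6L, max_lev)
  if (lev < 1L || lev > max_lev)
    stop_fbft(sprintf("'levels' must be in 1..%d for n = %d", max_lev, n),
              "fbft_parameter_error")
  n_use <- 2L^max_lev                     # truncate to a dyadic length
  v <- x[seq_len(n_use)]
  rows <- matrix(0, nrow = lev, ncol = n_use)
  for (l in seq_len(lev)) {
    st <- haar_step(v)
    # piecewise-constant rendering: each coefficient spans 2^l samples
    rows[l, ] <- rep(abs(st$detail), each = 2L^l)[seq_len(n_use)]
    v <- st$approx
  }
  # level l detail covers the band (fs/2^(l+1), fs/2^l]; use its midpoint
  band_mid <- 3 * fs / 2^(seq_len(lev) + 2L)
  ord <- order(band_mid)
  tf_map(rows[ord, , drop = FALSE],
         freqs = band_mid[ord],
         times = (seq_len(n_use) - 1L) / fs,
         meta = list(transform = "dwt", fs = fs, wavelet = "haar",
                     levels = lev))
}

tf_power_spectrum <- function(x, fs) {
  n <- length(x)
  nb <- n %/% 2L + 1L
  X <- Mod(stats::fft(x))[seq_len(nb)]^2 / n^2    # two-sided power
  psd <- X
  # fold negative frequencies onto positive ones (one-sided convention)
  interior <- 2:(nb - 1L)
  if (n %% 2L == 0L) psd[interior] <- 2 * psd[interior]
  else if (nb >= 2L) psd[2:nb] <- 2 * psd[2:nb]
  df <- fs / n
  psd <- psd / df                          # density: sum(psd)*df = mean(x^2)
  tf_map(matrix(psd, ncol = 1L),
         freqs = (seq_len(nb) - 1L) * df,
         times = n / (2 * fs),
         meta = list(transform = "power_spectrum", fs = fs))
}
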