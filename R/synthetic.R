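#' Sinusoidal component with an activity interval
#'
#' One building block of a composite test signal: a sinusoid of amplitude
#' `amp` and frequency `freq` that is switched on over the half-open time
#' interval `[t_on, t_off)` and zero elsewhere.
#'
#' @param freq oscillation frequency in Hz (`>= 0`).
#' @param amp amplitude, arbitrary units (`>= 0`, default 1).
#' @param t_on,t_off activity interval in seconds, `0 <= t_on < t_off`.
#' @param phase initial phase in radians (default 0).
#' @return an object of class `fbft_component_spec`.
#' @export
component_spec <- function(freq, amp = 1, t_on = 0, t_off = Inf, phase = 0) {
  if (!is.numeric(freq) || freq < 0) stop_fbft("'freq' must be >= 0", "fbft_type_error")
  if (!is.numeric(amp) || amp < 0) stop_fbft("'amp' must be >= 0", "fbft_type_error")
  if (!(t_on >= 0 && t_on < t_off))
    stop_fbft("need 0 <= t_on < t_off", "fbft_type_error")
  structure(list(freq = freq, amp = amp, t_on = t_on, t_off = t_off,
                 phase = phase),
            class = "fbft_component_spec")
}

#' Generate a composite multi-sinusoid test signal
#'
#' The sample at time `t` is the sum over components of
#' `amp * sin(2*pi*freq*t + phase)` restricted to each component's activity
#' interval `[t_on, t_off)`, plus optional Gaussian noise. This is the
#' ground-truth fixture for time-frequency localization: within each
#' component's interval the dominant spectral ridge is known exactly.
#'
#' @param components list of [component_spec()] objects (may be empty).
#' @param fs sampling rate in Hz; must exceed twice the highest component
#'   frequency (Nyquist).
#' @param duration signal length in seconds (`> 0`).
#' @param noise_sd standard deviation of additive white Gaussian noise
#'   (default 0).
#' @param seed integer seed for the noise (ignored when `noise_sd = 0`).
#' @return a single-channel `fbft_signal` named `"synthetic"`.
#' @examples
#' s <- composite_signal(list(component_spec(10)), fs = 200, duration = 1)
#' @export
composite_signal <- function(components, fs, duration, noise_sd = 0, seed = 1L) {
  stopifnot(is.list(components), duration > 0, fs > 0, noise_sd >= 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (i in seq_along(components)) {
    cmp <- components[[i]]
    if (!inherits(cmp, "fbft_component_spec"))
      stop_fbft("every component must be a component_spec()", "fbft_type_error")
    if (cmp$freq > 0 && fs <= 2 * cmp$freq)
      stop_fbft(sprintf("component %d at %g Hz violates Nyquist for fs = %g Hz",
                        i, cmp$freq, fs), "fbft_parameter_error")
    active <- t >= cmp$t_on & t < cmp$t_off
    x[active] <- x[active] +
      cmp$amp * sin(2 * pi * cmp$freq * t[active] + cmp$phase)
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  signal(matrix(x, nrow = 1L), fs = fs, channel_names = "synthetic")
}

#' Latent-mix specification for correlated multi-channel surrogates
#'
#' Describes an EEG-like multi-channel recording in which every channel is
#' a weighted copy of one shared band-limited source plus independent
#' noise. Channels with large loadings are mutually correlated; a channel
#' with loading 0 carries only its own noise and is the planted
#' "unique-information" channel that mCC selection should rank lowest.
#'
#' @param n_channels number of channels (`>= 2`).
#' @param loadings numeric vector of per-channel weights on the latent
#'   source, length `n_channels`.
#' @param noise_sd per-channel independent noise standard deviation (`> 0`).
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param seed integer seed.
#' @return an object of class `fbft_latent_mix_spec`.
#' @export
latent_mix_spec <- function(n_channels = 4L, loadings = c(1, 1, 1, 0),
                            noise_sd = 0.3, fs = 250, duration = 20,
                            seed = 1L) {
  if (n_channels < 2L) stop_fbft("'n_channels' must be >= 2", "fbft_type_error")
  if (length(loadings) != n_channels)
    stop_fbft("length(loadings) must equal n_channels", "fbft_type_error")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_fbft("'noise_sd' must be > 0", "fbft_type_error")
  structure(list(n_channels = as.integer(n_channels), loadings = loadings,
                 noise_sd = noise_sd, fs = fs, duration = duration,
                 seed = as.integer(seed)),
            class = "fbft_latent_mix_spec")
}

# Brick-wall low-pass via FFT: keep |f| <= cutoff_hz, zero the rest.
lowpass_fft <- function(x, fs, cutoff_hz) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                  # two-sided frequency magnitude
  X[f > cutoff_hz] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a correlated multi-channel surrogate recording
#'
#' Channel `i` equals `loadings[i] * g(t) + e_i(t)` where `g` is white
#' Gaussian noise low-pass filtered to 0-40 Hz (an EEG-like spectrum,
#' without claiming physiological realism) and scaled to unit variance,
#' and `e_i` is independent Gaussian noise of standard deviation
#' `noise_sd`. Output is bit-reproducible for a given seed.
#'
#' @param spec an [latent_mix_spec()].
#' @return an `fbft_signal` with `spec$n_channels` channels.
#' @export
correlated_eeg <- function(spec) {
  stopifnot(inherits(spec, "fbft_latent_mix_spec"))
  n <- round(spec$duration * spec$fs)
  with_seed(spec$seed, {
    g <- lowpass_fft(stats::rnorm(n), spec$fs, cutoff_hz = 40)
    g <- g / stats::sd(g)
    m <- matrix(stats::rnorm(spec$n_channels * n, sd = spec$noise_sd),
                nrow = spec$n_channels)
    m <- m + outer(spec$loadings, g)
    signal(m, fs = spec$fs,
           channel_names = paste0("ch", seq_len(spec$n_channels)))
  })
}

#' Built-in synthetic presets
#'
#' `"fig4"` and `"fig6"` are the canonical worked example: three unit
#' sinusoids at 10, 20 and 60 Hz active over consecutive 1 s intervals
#' (`[0,1)`, `[1,2)`, `[2,3)` s) at `fs = 500` Hz, noiseless. Amplitudes,
#' interval boundaries, duration and sampling rate are this package's
#' fixed choices (documented in the methods vignette); the component
#' frequencies are the stated ones. `"eeg"` is the planted latent-mix
#' fixture of [latent_mix_spec()] defaults (4 channels, loadings
#' `1,1,1,0`, `noise_sd = 0.3`, 5000 samples).
#'
#' @param preset one of `"fig4"`, `"fig6"`, `"eeg"`.
#' @param seed integer seed passed to the generator.
#' @return an `fbft_signal`; the generation parameters are attached as
#'   attribute `"preset_params"`.
#' @export
preset_signal <- function(preset = c("fig4", "fig6", "eeg"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "eeg") {
    spec <- latent_mix_spec(seed = seed)
    out <- correlated_eeg(spec)
    attr(out, "preset_params") <- unclass(spec)
    return(out)
  }
  params <- list(freqs = c(10, 20, 60), amp = 1,
                 intervals = rbind(c(0, 1), c(1, 2), c(2, 3)),
                 fs = 500, duration = 3, noise_sd = 0)
  comps <- lapply(1:3, function(i)
    component_spec(params$freqs[i], amp = params$amp,
                   t_on = params$intervals[i, 1], t_off = params$intervals[i, 2]))
  out <- composite_signal(comps, fs = params$fs, duration = params$duration,
                          noise_sd = params$noise_sd, seed = seed)
  attr(out, "preset_params") <- params
  out
}
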