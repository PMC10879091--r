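---
title: "Forward-Backward Fourier Transform: method, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-Backward Fourier Transform: method, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbft)
```

## The problem

Clinical EEG and phonocardiogram review hinges on recognizing *when* an
oscillation is present, not only *that* it is present somewhere in a
recording. A plain Fourier spectrum pools the whole record, so a 10 Hz
burst in the first second and a 60 Hz burst in the last look identical to
two sustained tones. Windowed methods (STFT, wavelets) trade time against
frequency resolution through an explicit window scale. This package
implements a different construction, the Forward-Backward Fourier
Transform (FBFT), and the surrounding machinery needed to turn
multi-channel recordings into time-frequency (TF) images that a
convolutional classifier — or a clinician's eye — can consume.

## The transform

For a single-channel signal $x[0..n-1]$ sampled at $f_s$, fix a common FFT
length $P \ge n$ and define, for every time index $u$,

$$
X(f, u) \;=\; \min\!\Big(
  \big|\mathrm{FFT}_P\,x[0..u]\big|(f),\;
  \big|\mathrm{FFT}_P\,x[u..n-1]\big|(f)
\Big),
$$

the element-wise minimum of the zero-padded magnitude spectra of the
*prefix* up to $u$ and the *suffix* from $u$ (sample $u$ belongs to both
subarrays). The logic: a frequency component attains a large prefix
magnitude only once its activity has started, and a large suffix magnitude
only while its activity has not yet ended. Their minimum is therefore
non-negligible at $(f, u)$ only when the component is active *around* $u$
— components are pinned to their activity intervals, and incidental
harmonics that only one side contains are suppressed.

Two readings of the defining split exist: the integral form uses strict
inequalities ($t<u$, $t>u$, excluding sample $u$ from both sides), while
the procedural form slices inclusively on both sides. The package follows
the procedural form — `fbft()` column $u$ pairs `x[0..u]` with
`x[u..n-1]` — because it is the reading under which the cumulative-slice
procedure and the minimum rule coincide; at the signal lengths involved
the single shared sample is immaterial.

The minimum of two *complex* spectra is undefined; the transform is
defined on magnitudes, and phase is discarded. `fbft_tf_map` therefore
stores only a nonnegative magnitude matrix plus its axes.

### Numerical choices

* **Padding.** All subarrays share one frequency grid, `freqs[k] = k *
  fs / pad_len`. The default `pad_len` is the smallest power of two
  $\ge 2n$: padding must *extend* the signal (a `pad_len < n` is an
  error), a power of two keeps the FFT efficient, and the factor 2 gives
  sub-Hz bins at typical 1-3 s windows.
* **Raw vs normalized magnitudes.** Prefix/suffix magnitudes grow with
  subarray length, so the raw minimum is weighted toward the shorter
  side. The default keeps raw magnitudes (faithful to the defining
  procedure); `normalize = TRUE` divides each spectrum by its subarray
  length before the minimum, an opt-in for visualization.
* **Stride.** `stride = s` evaluates every $s$-th time index (always
  including the last). It is a pure restriction of the stride-1 map —
  the computed columns are identical — and exists because the naive cost
  is $O(n^2 \log n)$ per window; desk-scale windows ($n$ up to a few
  thousand) run in about a second at stride 1.
* **Dual-route verification.** `fbft_reference()` is a literal,
  unvectorized transcription of the defining procedure and `fbft()` must
  equal it to $10^{-12}$; both use R's FFT, so the *independent* check in
  the test suite is a brute-force $O(n^2)$ direct DFT that shares no code
  with either path. Further property tests pin the conventions:
  time-reversal flips the time axis, the map is absolutely homogeneous in
  amplitude, the map never exceeds either contributing spectrum, and FFT
  magnitude is invariant under circular time shift.
* **Ridges.** `ridge_frequencies()` reports the arg-max (excluding DC) of
  the time-averaged magnitude over an interval; an identically zero
  profile returns `NA` with a warning rather than an error, so batch
  summaries survive silent windows. On a discrete grid the arg-max of a
  leakage-tilted plateau can land one bin position away from the bin
  nearest the true frequency; "localized to within one bin" is therefore
  asserted in bin positions, not in Hz.

## Channel selection by mean correlation coefficient

For an $n$-channel recording the package computes the matrix of absolute
Pearson correlations between all channel pairs and each channel's mean
correlation coefficient (mCC), the arithmetic mean of its column —
diagonal included, since including the unit diagonal shifts every mCC
equally by $1/n$ and cannot change the ranking. Channels with *low* mCC
share the least linear structure with the montage and are kept
(`select_channels()`, default $k = 4$), on the rationale that highly
correlated channels mostly duplicate information. Decisions worth noting:

* A constant (dead) channel makes the correlation $0/0$; the package
  defines it as 0 with a warning, so dead channels rank as maximally
  unique and surface for review instead of crashing a batch.
* Correlation is computed once on the full cleaned recording per subject,
  not per analysis window.
* The selection is a screening heuristic. In clinical use it would be
  reviewed by a neurophysiologist; the pipeline exposes an explicit
  `channels` override instead of modeling that review.

## What the synthetic generators emulate

`preset_signal("fig4")` / `"fig6"` build the canonical worked example:
three unit sinusoids at 10, 20 and 60 Hz, each active over one of three
consecutive 1 s intervals. Only the three frequencies are prescribed by
the worked example; the remaining parameters are this package's fixed
choices, made once: amplitude 1 (a.u.), $f_s = 500$ Hz (comfortably above
Nyquist for 60 Hz and typical of clinical EEG), duration 3 s, no noise.
Components may overlap in time (they sum); activity intervals are
half-open.

`correlated_eeg()` builds multi-channel surrogates with planted
correlation structure: channel $i$ is $\lambda_i\,g(t) + e_i(t)$ with one
shared latent source $g$ (white Gaussian noise brick-wall low-passed to
0-40 Hz and scaled to unit variance — an EEG-like band, with no claim of
physiological realism) and independent Gaussian noise $e_i$. The default
fixture (4 channels, loadings $1,1,1,0$, `noise_sd = 0.3`, 5000 samples)
plants one channel carrying only its own noise; recovering it as the
lowest-mCC channel is the selection method's acceptance check. All
randomness flows through one explicit `seed`; generators restore the
caller's RNG state.

What a green test on these fixtures does **not** establish: performance on
real EEG (non-stationary, artifact-laden, volume-conducted), on murmur
audio, or any claim about classifier accuracy — classifier training is
out of scope entirely.

## Imaging pipeline

Recordings are segmented into fixed windows (`round(window_s * fs)`
samples; trailing partial windows are discarded because classifier inputs
must be equal-sized; starts at $k\,(\mathrm{window}-\mathrm{overlap})$ s).
Each selected channel's window is transformed, rendered to $[0,1]$ by
min-max normalization (optionally after $\log(1+m)$ compression, which
preserves ordering; an all-constant map renders as zeros), oriented with
frequency upward, and resampled by separable Catmull-Rom cubic
interpolation. Per-window normalization — rather than global — lets every
image use the full dynamic range and avoids amplitude leakage across
windows.

Composition into a three-plane image follows two modes: up to three
channels map positionally onto the red, green and blue planes (missing
planes zero); four or more channels are stacked vertically in channel
order and replicated to grayscale RGB — vertical stacking keeps one common
time axis along every row. The composite is resized to the configured
geometry (presets: 256x256x3, 224x224x3, 227x227x3 — kept as stated
configuration values, including the unconventional 256 for a network whose
stock input is 227). PNG encoding is done by a small deterministic
in-package encoder, so identical inputs produce byte-identical images and
manifests; the manifest records provenance (window start, channels, mode,
transform parameters) and an externally supplied label field.

## Baselines

`baseline_tf()` provides the comparison transforms on the same `tf_map`
container: a Hann-window STFT spectrogram, a Morlet ($\omega_0 = 6$)
scalogram on a log-spaced frequency grid, a Haar discrete-wavelet band map
rendered one row per decomposition level (a dyadic filter bank is not a
dense TF grid; each level row spans its band's midpoint), and a one-sided
periodogram scaled so `sum(psd) * df` equals the signal's mean square.
These are textbook methods with no prescribed parameterization, so
defaults are documented and configurable; none of them is the package's
contribution. The comparison harness asserts localization agreement (ridge
identity per activity interval) between FBFT and STFT on the worked
example, not magnitude agreement.

## Known limitations

* FBFT columns near the record edges are dominated by very short
  subarrays; interior columns are the informative ones.
* The raw-magnitude minimum biases ridge plateaus by up to about one bin
  under strong neighbouring-component leakage (see Numerical choices).
* EDF support covers plain EDF with a uniform sampling rate across
  channels; EDF+ annotations are not parsed. WAV murmur audio is consumed
  at its native rate; no resampling is applied or implied.
* The configuration front end accepts JSON (not YAML: no YAML parser is
  available in the supported dependency set).
* Runtime grows quadratically with window length at stride 1; use
  `stride` for long windows.
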