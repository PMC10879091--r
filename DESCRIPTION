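Package: fbft
Title: Forward-Backward Fourier Transform Time-Frequency Analysis for
    Biomedical Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-frequency analysis of multi-channel biomedical recordings
    (EEG, phonocardiogram) built around the Forward-Backward Fourier
    Transform (FBFT): for every time index, the element-wise minimum of the
    zero-padded FFT magnitudes of the signal prefix and suffix, which
    localizes oscillatory components jointly in time and frequency.
    Includes readers for EDF, delimited-text and WAV recordings, NaN
    cleaning and window segmentation, mean-correlation-coefficient (mCC)
    channel selection, baseline transforms (STFT spectrogram, Morlet
    scalogram, discrete-wavelet band map, power spectrum), synthetic
    composite-signal and correlated multi-channel generators, and a
    rendering pipeline that turns per-channel time-frequency maps into
    classifier-ready RGB or concatenated PNG images with a reproducible
    manifest.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
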