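#' Multi-channel uniformly sampled signal
#'
#' The common container for every recording handled by the package: a
#' channels-by-samples numeric matrix together with its sampling rate and
#' channel labels. EEG amplitudes are carried in their native units
#' (typically microvolts); audio is carried in arbitrary units in
#' `[-1, 1]`.
#'
#' @param samples numeric matrix, `n_channels x n_samples`. A plain vector
#'   is accepted for single-channel data and reshaped to one row.
#' @param fs sampling rate in Hz (`> 0`).
#' @param channel_names character vector of unique labels, one per row of
#'   `samples`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param t0 recording start offset in seconds (default 0). Window
#'   extraction sets this so each window remembers its position in the
#'   parent recording.
#'
#' @return an object of class `fbft_signal` with fields `samples`, `fs`,
#'   `channel_names`, `t0`.
#' @examples
#' s <- signal(rbind(sin(2 * pi * 10 * (0:99) / 100)), fs = 100)
#' n_samples(s)
#' duration(s)
#' @export
signal <- function(samples, fs, channel_names = NULL, t0 = 0) {
  if (is.vector(samples) && is.numeric(samples))
    samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_fbft("'samples' must be a numeric matrix (channels x samples)",
              "fbft_type_error")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_fbft("'fs' must be a single positive number (Hz)", "fbft_type_error")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop_fbft("signal needs at least 1 channel and 1 sample", "fbft_type_error")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples))
    stop_fbft("length(channel_names) must equal the number of channels",
              "fbft_type_error")
  if (anyDuplicated(channel_names))
    stop_fbft("channel names must be unique", "fbft_type_error")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop_fbft("'t0' must be a single finite number (seconds)", "fbft_type_error")
  dimnames(samples) <- NULL
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_names = channel_names, t0 = as.numeric(t0)),
    class = "fbft_signal"
  )
}

#' @rdname signal
#' @param x an `fbft_signal`.
#' @export
n_channels <- function(x) nrow(x$samples)

#' @rdname signal
#' @export
n_samples <- function(x) ncol(x$samples)

#' @rdname signal
#' @export
duration <- function(x) ncol(x$samples) / x$fs

#' @export
print.fbft_signal <- function(x, ...) {
  cat(sprintf("<fbft_signal> %d channel(s) x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              n_channels(x), n_samples(x), x$fs, duration(x), x$t0))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract named channels from a signal
#'
#' @param x an `fbft_signal`.
#' @param channels character vector of channel names (order preserved).
#' @return an `fbft_signal` restricted to the requested channels.
#' @export
select_signal_channels <- function(x, channels) {
  idx <- match(channels, x$channel_names)
  if (anyNA(idx))
    stop_fbft(paste0("unknown channel(s): ",
                     paste(channels[is.na(idx)], collapse = ", ")),
              "fbft_parameter_error")
  signal(x$samples[idx, , drop = FALSE], x$fs, x$channel_names[idx], x$t0)
}

#' Remove or fill non-finite samples
#'
#' Recordings occasionally carry NaN stretches (sensor drop-out, export
#' artifacts). Downstream transforms require finite input, so cleaning is
#' the first pipeline stage after reading.
#'
#' @param x an `fbft_signal`.
#' @param policy `"drop_samples"` removes every time index at which any
#'   channel is non-finite (keeps channels aligned); `"interpolate"` fills
#'   gaps per channel by linear interpolation, extending the nearest finite
#'   value at the record boundaries.
#' @return a cleaned `fbft_signal` with all samples finite.
#' @examples
#' s <- signal(c(0, NaN, 2), fs = 10)
#' clean_nans(s, "interpolate")$samples
#' @export
clean_nans <- function(x, policy = c("drop_samples", "interpolate")) {
  policy <- match.arg(policy)
  m <- x$samples
  bad <- !is.finite(m)
  if (!any(bad)) return(x)
  if (all(bad))
    stop_fbft("all samples are non-finite; nothing left after cleaning",
              "fbft_empty_signal_error")
  if (policy == "drop_samples") {
    keep <- !apply(bad, 2L, any)
    if (!any(keep))
      stop_fbft("every time index has a non-finite sample; nothing left after cleaning",
                "fbft_empty_signal_error")
    m <- m[, keep, drop = FALSE]
  } else {
    idx <- seq_len(ncol(m))
    for (i in seq_len(nrow(m))) {
      ok <- is.finite(m[i, ])
      if (all(ok)) next
      if (!any(ok))
        stop_fbft(sprintf("channel '%s' has no finite samples; cannot interpolate",
                          x$channel_names[i]),
                  "fbft_empty_signal_error")
      m[i, ] <- stats::approx(idx[ok], m[i, ok], xout = idx,
                              method = "linear", rule = 2)$y
    }
  }
  signal(m, x$fs, x$channel_names, x$t0)
}

#' Windowing specification
#'
#' Fixed window length and overlap, in seconds, used to slice recordings
#' into analysis frames (e.g. 1 s windows with 0.25 s overlap for
#' seizure-EEG imaging).
#'
#' @param window_s window length in seconds (`> 0`).
#' @param overlap_s overlap between consecutive windows in seconds
#'   (`0 <= overlap_s < window_s`).
#' @return an object of class `fbft_segment_spec`.
#' @export
segment_spec <- function(window_s, overlap_s = 0) {
  if (!is.numeric(window_s) || length(window_s) != 1L || !is.finite(window_s) ||
      window_s <= 0)
    stop_fbft("'window_s' must be a single positive number", "fbft_type_error")
  if (!is.numeric(overlap_s) || length(overlap_s) != 1L || !is.finite(overlap_s) ||
      overlap_s < 0 || overlap_s >= window_s)
    stop_fbft("'overlap_s' must satisfy 0 <= overlap_s < window_s",
              "fbft_type_error")
  structure(list(window_s = as.numeric(window_s),
                 overlap_s = as.numeric(overlap_s)),
            class = "fbft_segment_spec")
}

#' Slice a recording into fixed-length windows
#'
#' Windows start at `t = k * (window_s - overlap_s)` for `k = 0, 1, 2, ...`
#' for as long as a full window fits; each window has exactly
#' `round(window_s * fs)` samples and a trailing partial window is
#' discarded (fixed-size image generation downstream needs equal-length
#' frames). Time intervals are half-open `[start, start + window_s)`.
#'
#' @param x an `fbft_signal`.
#' @param spec an [segment_spec()].
#' @return list of `fbft_signal` windows; each carries its start time in
#'   `t0` (seconds from the parent recording start). A window longer than
#'   the recording yields an empty list with a warning so batch runs can
#'   skip short records.
#' @examples
#' s <- signal(matrix(rnorm(2560), 1), fs = 256)
#' length(segment(s, segment_spec(1, 0.25)))  # 13
#' @export
segment <- function(x, spec) {
  stopifnot(inherits(x, "fbft_signal"), inherits(spec, "fbft_segment_spec"))
  win_n <- round(spec$window_s * x$fs)
  n <- n_samples(x)
  if (win_n > n) {
    warning(sprintf("window (%g s = %d samples) longer than signal (%d samples); no windows produced",
                    spec$window_s, win_n, n), call. = FALSE)
    return(list())
  }
  hop_s <- spec$window_s - spec$overlap_s
  n_win <- floor((duration(x) - spec$window_s) / hop_s) + 1L
  out <- vector("list", n_win)
  kept <- 0L
  for (k in seq_len(n_win) - 1L) {
    start <- round(k * hop_s * x$fs)   # 0-based start sample
    if (start + win_n > n) break       # guard against rounding at the tail
    kept <- kept + 1L
    out[[kept]] <- signal(x$samples[, (start + 1L):(start + win_n), drop = FALSE],
                          x$fs, x$channel_names, t0 = x$t0 + start / x$fs)
  }
  out[seq_len(kept)]
}
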