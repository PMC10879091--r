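#' Time-frequency map container
#'
#' The common output type of every transform in the package (FBFT and the
#' baselines): a nonnegative magnitude matrix over an ascending frequency
#' axis (rows) and an ascending time axis (columns), plus the transform's
#' provenance in `meta`.
#'
#' @param magnitude numeric matrix `n_freq_bins x n_time_points`, all
#'   entries finite and `>= 0`.
#' @param freqs strictly increasing frequency axis in Hz, within
#'   `[0, fs/2]`.
#' @param times strictly increasing time axis in seconds.
#' @param meta named list: transform name and its parameters (pad length,
#'   stride, normalization flag, ...). Must contain `transform` and `fs`.
#' @return an object of class `fbft_tf_map`.
#' @export
tf_map <- function(magnitude, freqs, times, meta) {
  if (!is.matrix(magnitude) || !is.numeric(magnitude))
    stop_fbft("'magnitude' must be a numeric matrix", "fbft_type_error")
  if (any(!is.finite(magnitude)) || any(magnitude < 0))
    stop_fbft("magnitudes must be finite and >= 0", "fbft_type_error")
  if (length(freqs) != nrow(magnitude))
    stop_fbft("length(freqs) must equal nrow(magnitude)", "fbft_type_error")
  if (length(times) != ncol(magnitude))
    stop_fbft("length(times) must equal ncol(magnitude)", "fbft_type_error")
  if (length(freqs) > 1L && any(diff(freqs) <= 0))
    stop_fbft("'freqs' must be strictly increasing", "fbft_type_error")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_fbft("'times' must be strictly increasing", "fbft_type_error")
  if (!is.list(meta) || is.null(meta$transform) || is.null(meta$fs))
    stop_fbft("'meta' must be a list with at least 'transform' and 'fs'",
              "fbft_type_error")
  if (min(freqs) < 0 || max(freqs) > meta$fs / 2 + 1e-9)
    stop_fbft("'freqs' must lie within [0, fs/2]", "fbft_type_error")
  structure(list(magnitude = magnitude, freqs = as.numeric(freqs),
                 times = as.numeric(times), meta = meta),
            class = "fbft_tf_map")
}

#' @export
print.fbft_tf_map <- function(x, ...) {
  cat(sprintf("<fbft_tf_map> %s: %d freq bins [%g, %g] Hz x %d time points [%g, %g] s\n",
              x$meta$transform, nrow(x$magnitude), min(x$freqs), max(x$freqs),
              ncol(x$magnitude), min(x$times), max(x$times)))
  invisible(x)
}

#' Dominant ridge frequency over a time interval
#'
#' Averages the magnitude over the map columns whose times fall in
#' `interval` and reports the frequency of the arg-max, excluding the DC
#' bin. This quantifies the time-frequency localization claim: inside a
#' component's activity interval the ridge must sit at that component's
#' frequency.
#'
#' @param tf an `fbft_tf_map`.
#' @param interval length-2 numeric, half-open time range `[t0, t1)` in
#'   seconds; must intersect the map's time axis.
#' @param k number of ridges to return (default 1). For `k > 1` the top-k
#'   local spectral peaks of the time-averaged profile are returned in
#'   decreasing magnitude order.
#' @return numeric vector of ridge frequencies in Hz (length `<= k`);
#'   `NA_real_` with a warning when the averaged magnitude is identically
#'   zero (no ridge).
#' @export
ridge_frequencies <- function(tf, interval = range(tf$times), k = 1L) {
  stopifnot(inherits(tf, "fbft_tf_map"), length(interval) == 2L)
  cols <- which(tf$times >= interval[1] & tf$times < interval[2])
  if (length(cols) == 0L)
    cols <- which(tf$times >= interval[1] & tf$times <= interval[2])
  if (length(cols) == 0L)
    stop_fbft("interval does not intersect the map's time axis",
              "fbft_parameter_error")
  prof <- rowMeans(tf$magnitude[, cols, drop = FALSE])
  keep <- tf$freqs > 0                    # exclude DC
  prof <- prof[keep]
  freqs <- tf$freqs[keep]
  if (all(prof == 0)) {
    warning("time-averaged magnitude is identically zero: no ridge", call. = FALSE)
    return(NA_real_)
  }
  if (k <= 1L) return(freqs[which.max(prof)])
  # local maxima of the averaged profile, ranked by height
  n <- length(prof)
  left <- c(-Inf, prof[-n]); right <- c(prof[-1L], -Inf)
  peaks <- which(prof >= left & prof > right & prof > 0)
  if (length(peaks) == 0L) peaks <- which.max(prof)
  peaks <- peaks[order(prof[peaks], decreasing = TRUE)]
  freqs[utils::head(peaks, k)]
}

#' Write / read a TF map as a portable JSON container
#'
#' The on-disk layout is a single JSON object with keys `magnitude` (array
#' of rows, `n_freq_bins x n_time_points`, doubles), `freqs` (Hz),
#' `times` (seconds) and `meta` (transform name and parameters). The format
#' is self-describing and readable from any language with a JSON parser.
#'
#' @param tf an `fbft_tf_map`.
#' @param path output/input path (conventionally `*.tfmap.json`).
#' @return `write_tf_map()` returns `path` invisibly; `read_tf_map()`
#'   returns the `fbft_tf_map`.
#' @export
write_tf_map <- function(tf, path) {
  stopifnot(inherits(tf, "fbft_tf_map"))
  jsonlite::write_json(
    list(magnitude = tf$magnitude, freqs = tf$freqs, times = tf$times,
         meta = tf$meta),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tf_map
#' @export
read_tf_map <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- as.list(o$meta)
  mag <- o$magnitude
  if (!is.matrix(mag)) mag <- matrix(mag, nrow = length(o$freqs), byrow = TRUE)
  tf_map(mag, o$freqs, o$times, meta)
}
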