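#' Absolute Pearson correlation between two channels
#'
#' Computed directly from the defining formula: the mean-centered
#' cross-product divided by the product of root sums of squares, taken in
#' absolute value. The result is the strength of linear (anti)correlation
#' in `[0, 1]`, the building block of the channel-redundancy matrix.
#'
#' A constant sequence makes the correlation 0/0 (undefined); the value is
#' defined as 0 with a warning so that a dead channel ranks as maximally
#' unique and surfaces for human review rather than crashing a batch run.
#'
#' @param x1,x2 numeric vectors of equal length `>= 2`.
#' @return `|r|` in `[0, 1]`.
#' @examples
#' pearson_abs(1:10, -(1:10))  # 1: perfectly anticorrelated
#' @export
pearson_abs <- function(x1, x2) {
  if (length(x1) != length(x2) || length(x1) < 2L)
    stop_fbft("'x1' and 'x2' must have equal length >= 2", "fbft_parameter_error")
  d1 <- x1 - mean(x1)
  d2 <- x2 - mean(x2)
  denom <- sqrt(sum(d1^2) * sum(d2^2))
  if (denom == 0) {
    warning("constant channel: correlation undefined, returning 0", call. = FALSE)
    return(0)
  }
  min(abs(sum(d1 * d2)) / denom, 1)
}

#' Pairwise channel correlation matrix and mean correlation coefficients
#'
#' Builds the n-by-n matrix of absolute Pearson correlations between all
#' channel pairs (CorrMat) and each channel's mean correlation coefficient
#' (mCC), the arithmetic mean of its column with the unit diagonal
#' included. Including the diagonal shifts every mCC equally by `1/n`, so
#' the selection order is unaffected either way. Correlation is computed
#' on the full cleaned recording, not per analysis window.
#'
#' @param x an `fbft_signal` with at least 2 channels.
#' @return an object of class `fbft_correlation_summary` with fields
#'   `matrix` (n x n, dimnames = channel names), `mcc` (named numeric) and
#'   `channel_names`.
#' @export
correlation_summary <- function(x) {
  stopifnot(inherits(x, "fbft_signal"))
  nc <- n_channels(x)
  if (nc < 2L)
    stop_fbft("correlation summary needs at least 2 channels",
              "fbft_parameter_error")
  m <- diag(1, nc)
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      m[i, j] <- m[j, i] <- pearson_abs(x$samples[i, ], x$samples[j, ])
    }
  }
  # A zero-variance channel also has an undefined self-correlation; keep
  # the pairwise convention (0) on the diagonal for consistency.
  const <- apply(x$samples, 1L, function(v) sum((v - mean(v))^2) == 0)
  diag(m)[const] <- 0
  dimnames(m) <- list(x$channel_names, x$channel_names)
  mcc <- colMeans(m)
  structure(list(matrix = m, mcc = mcc, channel_names = x$channel_names),
            class = "fbft_correlation_summary")
}

#' @export
print.fbft_correlation_summary <- function(x, ...) {
  cat(sprintf("<fbft_correlation_summary> %d channels\n", length(x$mcc)))
  print(round(x$mcc, 4))
  invisible(x)
}

#' Select the least-redundant channels by mean correlation coefficient
#'
#' Channels with low mCC share the least linear structure with the rest of
#' the montage and therefore carry the most unique information; they are
#' the ones kept for feature extraction. Ties are broken by original
#' channel order.
#'
#' @param summary an [correlation_summary()] result.
#' @param k number of channels to select, `1 <= k <= n_channels`
#'   (default 4, a typical montage reduction).
#' @return character vector of `k` channel names in ascending mCC order.
#' @export
select_channels <- function(summary, k = 4L) {
  stopifnot(inherits(summary, "fbft_correlation_summary"))
  n <- length(summary$mcc)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n)
    stop_fbft(sprintf("'k' must be in 1..%d", n), "fbft_parameter_error")
  ord <- order(summary$mcc, seq_len(n))   # stable: ties keep original order
  summary$channel_names[ord[seq_len(k)]]
}
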