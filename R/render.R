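#' Rendering specification for TF images
#'
#' @param out_size integer length-2 `(height, width)` in pixels, or `NULL`
#'   to keep the map's native resolution. The CNN-geometry presets used in
#'   practice are `c(256, 256)`, `c(224, 224)` and `c(227, 227)`.
#' @param colormap named monotone-intensity mapping applied when a
#'   single-channel image is exported on its own: `"gray"` (default) or
#'   `"hot"`. Composite images use channel-per-plane coloring instead.
#' @param log_scale apply `log(1 + m)` compression before normalization
#'   (default `FALSE`); the mapping stays monotone.
#' @return an object of class `fbft_render_spec`.
#' @export
render_spec <- function(out_size = c(224L, 224L), colormap = c("gray", "hot"),
                        log_scale = FALSE) {
  colormap <- match.arg(colormap)
  if (!is.null(out_size)) {
    if (length(out_size) != 2L || any(out_size < 1L))
      stop_fbft("'out_size' must be two positive integers (height, width)",
                "fbft_parameter_error")
    out_size <- as.integer(out_size)
  }
  structure(list(out_size = out_size, colormap = colormap,
                 log_scale = isTRUE(log_scale)),
            class = "fbft_render_spec")
}

# Separable Catmull-Rom cubic interpolation weights from n_in samples onto
# n_out samples (edge-clamped). Returns an n_out x n_in weight matrix, so a
# resize is two matrix products.
cubic_weights <- function(n_out, n_in) {
  kern <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
           ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
  }
  w <- matrix(0, n_out, n_in)
  if (n_in == 1L) { w[, 1L] <- 1; return(w) }
  # map output pixel centers onto input pixel centers
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  for (i in seq_len(n_out)) {
    base <- floor(pos[i])
    idx <- base + (-1:2)
    wt <- kern(pos[i] - idx)
    idx <- pmin(pmax(idx, 0L), n_in - 1L)   # clamp at the borders
    for (k in 1:4) w[i, idx[k] + 1L] <- w[i, idx[k] + 1L] + wt[k]
  }
  sweep(w, 1L, rowSums(w), "/")
}

#' Resize a matrix or image array by cubic interpolation
#'
#' Separable Catmull-Rom bicubic resampling, the interpolation used to fit
#' TF images to fixed CNN input geometries.
#'
#' @param img numeric matrix or `H x W x k` array.
#' @param out_size integer `(height, width)`.
#' @param clamp01 clip the (possibly overshooting) cubic output back into
#'   `[0, 1]` (default `TRUE`).
#' @return resized matrix/array of dimension `out_size` (x `k`).
#' @export
resize_bicubic <- function(img, out_size, clamp01 = TRUE) {
  stopifnot(length(out_size) == 2L, all(out_size >= 1L))
  one <- function(m) {
    wr <- cubic_weights(out_size[1], nrow(m))
    wc <- cubic_weights(out_size[2], ncol(m))
    wr %*% m %*% t(wc)
  }
  out <- if (is.matrix(img)) one(img)
  else {
    planes <- lapply(seq_len(dim(img)[3]), function(k) one(img[, , k]))
    array(unlist(planes), c(out_size, dim(img)[3]))
  }
  if (clamp01) out <- pmin(pmax(out, 0), 1)
  out
}

#' Render a TF map as a single-channel intensity image
#'
#' Magnitudes are optionally log-compressed (`log(1 + m)`), min-max
#' normalized to `[0, 1]` over the whole map (an all-constant map renders
#' as zeros), oriented with frequency increasing upward and time increasing
#' rightward, and resampled to `spec$out_size` by cubic interpolation.
#' Normalization is per map (per window), so each exported image uses the
#' full dynamic range.
#'
#' @param tf an `fbft_tf_map`.
#' @param spec an [render_spec()].
#' @return numeric matrix in `[0, 1]` of size `spec$out_size` (or the
#'   map's native size when `out_size` is `NULL`); row 1 is the highest
#'   frequency.
#' @export
render_tf <- function(tf, spec = render_spec()) {
  stopifnot(inherits(tf, "fbft_tf_map"), inherits(spec, "fbft_render_spec"))
  m <- tf$magnitude
  if (spec$log_scale) m <- log1p(m)
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(m), ncol(m))
  img <- m[rev(seq_len(nrow(m))), , drop = FALSE]   # freq increases upward
  if (!is.null(spec$out_size)) img <- resize_bicubic(img, spec$out_size)
  img
}

# monotone-luminance colormaps for standalone single-channel export
apply_colormap <- function(img, colormap = "gray") {
  h <- nrow(img); w <- ncol(img)
  v <- as.vector(img)
  rgb <- switch(colormap,
    gray = cbind(v, v, v),
    hot = cbind(pmin(3 * v, 1), pmin(pmax(3 * v - 1, 0), 1),
                pmin(pmax(3 * v - 2, 0), 1)),
    stop_fbft(sprintf("unknown colormap '%s'", colormap), "fbft_parameter_error"))
  array(rgb, c(h, w, 3L))
}
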