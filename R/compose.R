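#' Compose per-channel TF images into one classifier-ready composite
#'
#' Two composition modes turn the selected channels' single-channel TF
#' images into one `H x W x 3` array:
#' * `"rgb"` — up to three channel images become the red, green and blue
#'   planes positionally; missing planes are zero-filled. More than three
#'   channels cannot be packed into RGB — use `"concat"`.
#' * `"concat"` — channel images are stacked vertically in channel order
#'   (preserving a common time axis along each row), then the grayscale
#'   stack is replicated across the three planes.
#'
#' @param images ordered list of equally sized numeric matrices in
#'   `[0, 1]` (one per channel, e.g. from [render_tf()]).
#' @param mode `"rgb"` or `"concat"`.
#' @param channel_names optional character vector recorded in the
#'   provenance.
#' @return an object of class `fbft_composite_image` with fields `pixels`
#'   (`H x W x 3`, in `[0, 1]`) and `provenance` (mode, channel names and
#'   the plane/row mapping).
#' @export
compose_channels <- function(images, mode = c("rgb", "concat"),
                             channel_names = NULL) {
  mode <- match.arg(mode)
  if (!is.list(images) || length(images) < 1L)
    stop_fbft("'images' must be a non-empty list of matrices",
              "fbft_parameter_error")
  if (!all(vapply(images, is.matrix, TRUE)))
    stop_fbft("every image must be a numeric matrix", "fbft_parameter_error")
  dims <- vapply(images, dim, integer(2L))
  if (mode == "rgb" && length(images) > 3L)
    stop_fbft("rgb mode takes at most 3 channel images; use mode = 'concat' for more",
              "fbft_parameter_error")
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_fbft("all channel images must have identical dimensions",
              "fbft_parameter_error")
  channel_names <- channel_names %||% paste0("ch", seq_along(images))
  if (mode == "rgb") {
    h <- dims[1, 1]; w <- dims[2, 1]
    px <- array(0, c(h, w, 3L))
    for (i in seq_along(images)) px[, , i] <- images[[i]]
    mapping <- stats::setNames(c("red", "green", "blue")[seq_along(images)],
                               channel_names)
  } else {
    stack <- do.call(rbind, images)
    px <- array(rep(stack, 3L), c(dim(stack), 3L))
    mapping <- stats::setNames(paste0("rows ", seq_along(images)), channel_names)
  }
  structure(list(pixels = px,
                 provenance = list(mode = mode, channels = channel_names,
                                   mapping = mapping)),
            class = "fbft_composite_image")
}

#' @export
print.fbft_composite_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fbft_composite_image> %d x %d x 3 (%s of %s)\n",
              d[1], d[2], x$provenance$mode,
              paste(x$provenance$channels, collapse = ", ")))
  invisible(x)
}
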