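# End-to-end per-window image export: segment -> transform -> render ->
# compose -> PNG + JSON manifest.

# transform dispatcher shared by export_dataset() and the pipeline runner
apply_transform <- function(ch_signal, transform, transform_args) {
  if (identical(transform, "fbft")) {
    do.call(fbft, c(list(ch_signal), transform_args))
  } else {
    spec <- do.call(baseline_spec, c(list(method = transform), transform_args))
    baseline_tf(ch_signal, spec = spec)
  }
}

#' Export a recording as classifier-ready composite TF images
#'
#' Runs the per-window image pipeline: slice the selected channels into
#' windows, transform each channel of each window, render, compose
#' (RGB planes for up to 3 channels, vertical concatenation otherwise),
#' resize the composite to the target geometry, and write one PNG per
#' window plus a JSON manifest describing every image. Output is fully
#' deterministic: rerunning with the same inputs produces byte-identical
#' images and manifest.
#'
#' @param x an `fbft_signal` (cleaned; use [clean_nans()] first if needed).
#' @param channels channel names to use (default: all, in signal order).
#' @param seg an [segment_spec()].
#' @param transform `"fbft"` (default) or a baseline method name
#'   (`"stft"`, `"cwt"`, `"dwt"`, `"power_spectrum"`).
#' @param transform_args named list of extra arguments for the transform
#'   (e.g. `list(stride = 4)` for fbft).
#' @param render an [render_spec()]; `out_size` is the final composite
#'   geometry.
#' @param mode `"rgb"`, `"concat"`, or `"auto"` (default: rgb for up to 3
#'   channels, concat otherwise).
#' @param out_dir output directory (created if missing).
#' @param subject identifier used in file names (default `"subject"`).
#' @param labels optional label string stored with every manifest row
#'   (supplied externally; the pipeline does not label data).
#' @return the manifest as a data.frame (also written to
#'   `manifest.json` in `out_dir`), invisibly. An empty window list yields
#'   an empty manifest with a warning.
#' @export
export_dataset <- function(x, channels = NULL, seg, transform = "fbft",
                           transform_args = list(), render = render_spec(),
                           mode = c("auto", "rgb", "concat"),
                           out_dir, subject = "subject", labels = NA_character_) {
  stopifnot(inherits(x, "fbft_signal"), inherits(seg, "fbft_segment_spec"),
            inherits(render, "fbft_render_spec"))
  mode <- match.arg(mode)
  channels <- channels %||% x$channel_names
  x <- select_signal_channels(x, channels)
  if (mode == "auto") mode <- if (length(channels) <= 3L) "rgb" else "concat"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  windows <- segment(x, seg)
  rows <- vector("list", length(windows))
  if (length(windows) == 0L)
    warning("no windows produced; writing an empty manifest", call. = FALSE)
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    imgs <- lapply(seq_along(channels), function(i) {
      ch <- signal(win$samples[i, , drop = FALSE], win$fs, channels[i], win$t0)
      render_tf(apply_transform(ch, transform, transform_args), render)
    })
    comp <- compose_channels(imgs, mode, channel_names = channels)
    px <- comp$pixels
    if (!is.null(render$out_size) &&
        !identical(dim(px)[1:2], as.integer(render$out_size)))
      px <- resize_bicubic(px, render$out_size)
    file <- sprintf("%s_w%04d_t%07.3f_%s.png", subject, w - 1L, win$t0, transform)
    write_png(px, file.path(out_dir, file))
    rows[[w]] <- data.frame(
      file = file, window = w - 1L, start_s = win$t0,
      window_s = seg$window_s, overlap_s = seg$overlap_s,
      channels = paste(channels, collapse = "|"), mode = mode,
      transform = transform, height = dim(px)[1], width = dim(px)[2],
      label = labels, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
  else data.frame(file = character(), window = integer(), start_s = numeric(),
                  window_s = numeric(), overlap_s = numeric(),
                  channels = character(), mode = character(),
                  transform = character(), height = integer(),
                  width = integer(), label = character(),
                  stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
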