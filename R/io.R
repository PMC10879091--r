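#' Read a multi-channel recording into a signal
#'
#' Normalizes the three supported on-disk formats to the single
#' [signal()] container: EDF (European Data Format, the standard EEG
#' container), PCM WAV (heart-sound audio), and delimited text with one
#' column per channel and a header row of channel names (headband EEG
#' exports). Channel order is preserved from the file.
#'
#' Delimited text carries no sampling rate, so `fs` is required for
#' `format = "csv"` and is never guessed; EDF and WAV carry `fs` in their
#' headers.
#'
#' @param path file path.
#' @param format one of `"edf"`, `"csv"`, `"wav"`. Defaults to the file
#'   extension.
#' @param fs sampling rate in Hz; required for csv, ignored otherwise.
#' @param delim field delimiter for csv (default `","`).
#' @return an `fbft_signal`.
#' @seealso [write_signal_csv()], [write_edf()], [write_wav()]
#' @export
read_signal <- function(path, format = c("auto", "edf", "csv", "wav"),
                        fs = NULL, delim = ",") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", wav = "wav",
                     csv = , tsv = , txt = "csv",
                     stop_fbft(sprintf("cannot infer format from extension '%s'; pass 'format'", ext),
                               "fbft_format_error"))
  }
  if (!file.exists(path))
    stop_fbft(sprintf("cannot read '%s': no such file", path), "fbft_io_error")
  switch(format,
         edf = read_edf(path),
         wav = read_wav(path),
         csv = read_signal_csv(path, fs = fs, delim = delim))
}

read_signal_csv <- function(path, fs, delim = ",") {
  if (is.null(fs))
    stop_fbft("csv input carries no sampling rate: 'fs' must be supplied",
              "fbft_config_error")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                      colClasses = "numeric"),
    error = function(e)
      stop_fbft(sprintf("cannot parse '%s' as delimited text: %s", path,
                        conditionMessage(e)), "fbft_format_error"))
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop_fbft(sprintf("'%s' contains no data", path), "fbft_format_error")
  signal(t(as.matrix(df)), fs = fs, channel_names = colnames(df))
}

#' Write a signal as delimited text
#'
#' One column per channel, header row of channel names, full double
#' precision (round-trips through [read_signal()] to `<= 1e-9` relative).
#'
#' @param x an `fbft_signal`.
#' @param path output path.
#' @param delim field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "fbft_signal"))
  df <- as.data.frame(t(x$samples))
  names(df) <- x$channel_names
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
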