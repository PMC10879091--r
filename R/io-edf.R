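# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores 16-bit little-endian integers in fixed-duration data records,
# one block of samples per signal per record, with an ASCII header that
# carries the physical/digital calibration per signal. No R package in the
# supported stack reads EDF, so the format is parsed directly here. Only
# plain EDF with a uniform sampling rate across channels is supported
# (EDF+ annotations are out of scope).

edf_field <- function(raw, from, width) {
  trimws(rawToChar(raw[from:(from + width - 1L)]))
}

edf_num <- function(raw, from, width) {
  v <- suppressWarnings(as.numeric(edf_field(raw, from, width)))
  if (is.na(v)) stop_fbft("malformed EDF header field", "fbft_format_error")
  v
}

#' Read an EDF recording
#'
#' @param path path to a plain EDF file.
#' @return an `fbft_signal` with physical (calibrated) sample values and
#'   channel names from the EDF signal labels.
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop_fbft(sprintf("cannot read '%s': no such file", path), "fbft_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L)
    stop_fbft(sprintf("'%s' is too short to be EDF", path), "fbft_format_error")
  n_records <- edf_num(hdr, 237L, 8L)
  rec_dur <- edf_num(hdr, 245L, 8L)
  ns <- as.integer(edf_num(hdr, 253L, 4L))
  if (ns < 1L) stop_fbft("EDF file declares no signals", "fbft_format_error")
  shdr <- readBin(con, "raw", 256L * ns)
  if (length(shdr) < 256L * ns)
    stop_fbft("truncated EDF signal header", "fbft_format_error")
  fld <- function(width, offset) {
    vapply(seq_len(ns) - 1L,
           function(i) edf_field(shdr, offset * ns + i * width + 1L, width), "")
  }
  labels <- fld(16L, 0L)
  # per-signal numeric header blocks, laid out field-major
  num_at <- function(start_bytes, width) {
    vapply(seq_len(ns) - 1L, function(i) {
      v <- suppressWarnings(as.numeric(
        edf_field(shdr, start_bytes + i * width + 1L, width)))
      if (is.na(v)) stop_fbft("malformed EDF signal header", "fbft_format_error")
      v
    }, 0)
  }
  base <- ns * (16L + 80L + 8L)            # after label/transducer/dimension
  phys_min <- num_at(base, 8L)
  phys_max <- num_at(base + 8L * ns, 8L)
  dig_min  <- num_at(base + 16L * ns, 8L)
  dig_max  <- num_at(base + 24L * ns, 8L)
  spr <- as.integer(num_at(base + 32L * ns + 80L * ns, 8L))  # samples/record
  if (length(unique(spr)) != 1L)
    stop_fbft("EDF signals with differing sampling rates are not supported",
              "fbft_format_error")
  if (rec_dur <= 0)
    stop_fbft("EDF record duration must be positive", "fbft_format_error")
  fs <- spr[1L] / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - dig_min * scale
  n_total <- n_records * spr[1L]
  out <- matrix(NA_real_, nrow = ns, ncol = n_total)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = spr[1L] * ns, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < spr[1L] * ns)
      stop_fbft("truncated EDF data record", "fbft_format_error")
    for (s in seq_len(ns)) {
      dig <- block[((s - 1L) * spr[1L] + 1L):(s * spr[1L])]
      out[s, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <- dig * scale[s] + offset[s]
    }
  }
  signal(out, fs = fs, channel_names = make.unique(labels))
}

#' Write a signal as plain EDF
#'
#' Intended for fixtures and interchange: samples are quantized to the
#' EDF 16-bit digital range per channel, so the round trip is exact only
#' up to quantization (about 1/65000 of each channel's amplitude range).
#' The whole recording is written as one data record per second where
#' possible, else as a single record.
#'
#' @param x an `fbft_signal`; `x$fs` must make `n_samples / fs` give an
#'   integer number of 1 s records, otherwise one record holding the whole
#'   signal is written.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  stopifnot(inherits(x, "fbft_signal"))
  ns <- n_channels(x)
  n <- n_samples(x)
  if (n %% x$fs == 0 && x$fs == round(x$fs)) {
    spr <- as.integer(x$fs); n_rec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / x$fs
  }
  phys_min <- apply(x$samples, 1L, min)
  phys_max <- apply(x$samples, 1L, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  pad <- function(v, w) {
    s <- formatC(as.character(v), width = -w)
    s <- substr(s, 1L, w)
    formatC(s, width = -w)
  }
  num8 <- function(v) pad(signif(v, 7), 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8L), pad("X X X X", 80L), pad("Startdate X X X X", 80L),
    pad("01.01.00", 8L), pad("00.00.00", 8L),
    pad(as.character(256L * (1L + ns)), 8L), pad("", 44L),
    pad(as.character(n_rec), 8L), num8(rec_dur), pad(as.character(ns), 4L)),
    con, eos = NULL)
  writeChar(paste0(
    paste0(pad(x$channel_names, 16L), collapse = ""),
    paste0(rep(pad("", 80L), ns), collapse = ""),
    paste0(rep(pad("uV", 8L), ns), collapse = ""),
    paste0(num8(phys_min), collapse = ""),
    paste0(num8(phys_max), collapse = ""),
    paste0(rep(pad("-32768", 8L), ns), collapse = ""),
    paste0(rep(pad("32767", 8L), ns), collapse = ""),
    paste0(rep(pad("", 80L), ns), collapse = ""),
    paste0(rep(pad(as.character(spr), 8L), ns), collapse = ""),
    paste0(rep(pad("", 32L), ns), collapse = "")),
    con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- x$samples[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- round((seg - phys_min[s]) / scale[s]) + dig_min
      dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
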