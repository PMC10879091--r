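# Minimal RIFF/WAV reader/writer (PCM integer and IEEE float), used for
# heart-sound audio. Samples are normalized to [-1, 1) arbitrary units.

#' Read a WAV audio file
#'
#' Supports PCM 8/16/24/32-bit integer and 32/64-bit IEEE float, mono or
#' multi-channel. Integer samples are scaled to `[-1, 1)`.
#'
#' @param path path to a WAV file.
#' @return an `fbft_signal` with channels named `"ch1"`, `"ch2"`, ...
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop_fbft(sprintf("cannot read '%s': no such file", path), "fbft_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  size <- readBin(con, "integer", 1L, 4L, endian = "little")
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_fbft(sprintf("'%s' is not a RIFF/WAVE file", path), "fbft_format_error")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    csize <- readBin(con, "integer", 1L, 4L, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- readBin(con, "raw", csize)
    } else if (tag == "data") {
      data <- readBin(con, "raw", csize)
    } else {
      seek(con, csize + csize %% 2L, origin = "current")
      next
    }
    if (csize %% 2L == 1L) seek(con, 1L, origin = "current")
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data))
    stop_fbft(sprintf("'%s': missing fmt or data chunk", path), "fbft_format_error")
  u16 <- function(off) sum(as.integer(fmt[off + 1:2]) * c(1L, 256L))
  u32 <- function(off) sum(as.numeric(fmt[off + 1:4]) * 256^(0:3))
  audio_fmt <- u16(0L); n_ch <- u16(2L); fs <- u32(4L); bits <- u16(14L)
  if (audio_fmt == 65534L) audio_fmt <- u16(24L)  # WAVE_FORMAT_EXTENSIBLE
  bytes <- bits %/% 8L
  n_frames <- length(data) %/% (bytes * n_ch)
  if (audio_fmt == 3L) {
    x <- readBin(data, "double", n = n_frames * n_ch, size = bytes,
                 endian = "little")
  } else if (audio_fmt == 1L) {
    if (bits == 8L) {
      x <- (as.integer(readBin(data, "integer", n = n_frames * n_ch, size = 1L,
                               signed = FALSE)) - 128) / 128
    } else if (bits == 24L) {
      b <- matrix(as.integer(data[seq_len(n_frames * n_ch * 3L)]), nrow = 3L)
      v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else {
      x <- readBin(data, "integer", n = n_frames * n_ch, size = bytes,
                   signed = TRUE, endian = "little") / 2^(bits - 1L)
    }
  } else {
    stop_fbft(sprintf("'%s': unsupported WAV encoding (format tag %d)",
                      path, audio_fmt), "fbft_format_error")
  }
  samples <- matrix(x, nrow = n_ch)   # frames are interleaved by channel
  signal(samples, fs = fs)
}

#' Write a signal as 16-bit PCM WAV
#'
#' Values are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param x an `fbft_signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "fbft_signal"))
  n_ch <- n_channels(x); n <- n_samples(x)
  pcm <- as.integer(round(pmin(pmax(as.vector(x$samples), -1), 32767 / 32768) * 32768))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(n_ch); w32(round(x$fs))
  w32(round(x$fs) * n_ch * 2L); w16(n_ch * 2L); w16(16L)
  writeChar("data", con, eos = NULL); w32(data_bytes)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
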