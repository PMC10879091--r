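# Minimal PNG encoder (8-bit RGB, no interlace, filter type 0).
#
# No package in the supported dependency set writes raw pixel arrays to
# PNG, and rendering through a graphics device is not guaranteed to be
# pixel-exact, which would break the byte-identical-output contract of the
# export pipeline. PNG's IDAT payload is a zlib stream, which base R
# provides via memCompress(); only the per-chunk CRC-32 is implemented
# here.

# CRC-32 in double arithmetic. R's 32-bit integers cannot hold 0x80000000
# (INT_MIN encodes NA), so all 32-bit values are kept as doubles in
# [0, 2^32) and XORed via 16-bit halves.
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256L)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (c %% 2 == 1) xor32(c %/% 2, 3988292384) else c %/% 2  # 0xEDB88320
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwXor(crc %% 256, b)
    crc <- xor32(crc %/% 256, tab[idx + 1L])
  }
  xor32(crc, 4294967295)
}

u32be <- function(v) {
  v <- as.numeric(v) %% 2^32
  as.raw(c(v %/% 2^24, (v %/% 2^16) %% 256, (v %/% 256) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body) %% 2^32
  c(u32be(length(data)), body, u32be(crc))
}

#' Write an RGB pixel array as a PNG file
#'
#' Deterministic 8-bit RGB PNG encoder: identical pixel input always
#' produces identical bytes.
#'
#' @param pixels numeric array `H x W x 3` with values in `[0, 1]`, or an
#'   `H x W` matrix (written as gray by replicating the plane).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(pixels, path) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop_fbft("'pixels' must be an H x W x 3 array", "fbft_parameter_error")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop_fbft("pixel values must be finite and in [0, 1]", "fbft_parameter_error")
  h <- d[1]; w <- d[2]
  bytes <- as.integer(round(pixels * 255))
  # interleave planes per pixel, row-major, prefixing each scanline with
  # filter byte 0
  rgb <- aperm(array(bytes, c(h, w, 3L)), c(3L, 2L, 1L))  # [plane, col, row]
  scan <- matrix(as.vector(rgb), nrow = 3L * w)           # column = one row
  raster <- rbind(0L, scan)                               # filter bytes
  idat <- memCompress(as.raw(raster), type = "gzip")
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
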