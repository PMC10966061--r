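# Minimal 16-bit grayscale PNG writer. The png package reads 16-bit
# samples exactly but silently quantizes to 8 bits on write, which would
# destroy the quantizer's decision margin; this writer emits bit-exact
# 16-bit samples (color type 0, no interlace, filter 0).

png_crc_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8) {
      # R's bitwShiftR is a logical shift on the 32-bit pattern
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

png_crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(png_crc_table[idx + 1L], bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  (as.numeric(crc) + 2^32) %% 2^32
}

png_uint32be <- function(v) {
  v <- as.numeric(v)
  as.raw(c((v %/% 16777216) %% 256, (v %/% 65536) %% 256,
           (v %/% 256) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(png_uint32be(length(data)), body, png_uint32be(png_crc32(body)))
}

# pixels: integer matrix (rows x cols) in [0, 65535]
png_write_gray16 <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  v <- as.numeric(t(pixels))  # row-major scanlines
  hi <- as.raw(v %/% 256)
  lo <- as.raw(v %% 256)
  samples <- as.vector(rbind(hi, lo))  # big-endian sample bytes
  dim(samples) <- NULL
  rows <- split(samples, rep(seq_len(h), each = 2L * w))
  raw_stream <- unlist(lapply(rows, function(r) c(as.raw(0L), r)), use.names = FALSE)
  idat <- memCompress(raw_stream, type = "gzip")
  ihdr <- c(png_uint32be(w), png_uint32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate, filter0, no interlace
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
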