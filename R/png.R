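# Minimal 8-bit grayscale PNG codec.  No PNG package exists in the target R
# stack, so the writer emits colour-type-0 PNGs (filter 0 scanlines, one zlib
# IDAT) and the reader handles any of the five scanline filters.  zlib
# (de)compression comes from memCompress/memDecompress, which operate on
# zlib-wrapped streams -- exactly the PNG IDAT format.

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) bitwXor_dbl(3988292384, floor(c / 2))
           else floor(c / 2)
    }
    tab[n + 1] <- c
  }
  .crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- 4294967295
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(c %% 256), b[i]) + 1L
    c <- bitwXor_dbl(tab[idx], floor(c / 256))
  }
  bitwXor_dbl(c, 4294967295)
}

# 32-bit xor on doubles (R's bitwXor is limited to ints)
bitwXor_dbl <- function(a, b) {
  hi <- bitwXor(floor(a / 65536), floor(b / 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}

u32_bytes <- function(x) {
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}
bytes_u32 <- function(b) {
  sum(as.numeric(b) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), body, u32_bytes(crc32(body)))
}

#' Write an 8-bit grayscale PNG
#'
#' @param mat integer matrix of intensities in 0..255 (rows = image rows)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_png_gray <- function(mat, path) {
  if (!is.matrix(mat)) stopf("mat must be a matrix")
  v <- round(mat)
  if (any(v < 0 | v > 255)) stopf("intensities must be in 0..255")
  h <- nrow(v); w <- ncol(v)
  # scanlines: filter byte 0 + row bytes
  scan <- cbind(0L, matrix(as.integer(t(v)), nrow = h, byrow = TRUE))
  raw_data <- as.raw(as.vector(t(scan)))
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(8L, 0L, 0L, 0L, 0L)))  # depth 8, gray, deflate, none, none
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(raw_data, "gzip")),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' @param path PNG file path (colour type 0, bit depth 8, non-interlaced)
#' @return integer matrix of intensities in 0..255
#' @export
read_png_gray <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  if (length(bytes) < 8 || !identical(bytes[1:8], sig))
    stopf("not a PNG file: %s", path)
  pos <- 9L
  w <- h <- NULL
  idat <- raw()
  while (pos + 7 <= length(bytes)) {
    len <- bytes_u32(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw()
    if (type == "IHDR") {
      w <- bytes_u32(data[1:4]); h <- bytes_u32(data[5:8])
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      interlace <- as.integer(data[13])
      if (depth != 8L || ctype != 0L || interlace != 0L)
        stopf("only 8-bit non-interlaced grayscale PNG supported (depth=%d, colour=%d)",
              depth, ctype)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(w)) stopf("PNG missing IHDR")
  dec <- as.integer(memDecompress(idat, "gzip"))
  stride <- w + 1L
  if (length(dec) != h * stride) stopf("PNG data size mismatch")
  rows <- matrix(dec, nrow = h, ncol = stride, byrow = TRUE)
  out <- matrix(0L, nrow = h, ncol = w)
  prev <- integer(w)
  for (i in seq_len(h)) {
    ft <- rows[i, 1]
    cur <- rows[i, -1]
    cur <- unfilter_scanline(cur, prev, ft)
    out[i, ] <- cur
    prev <- cur
  }
  storage.mode(out) <- "integer"
  out
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

unfilter_scanline <- function(cur, prev, ft) {
  w <- length(cur)
  if (ft == 0L) return(cur)
  if (ft == 2L) return((cur + prev) %% 256L)
  out <- integer(w)
  for (j in seq_len(w)) {
    left <- if (j > 1L) out[j - 1L] else 0L
    up <- prev[j]
    ul <- if (j > 1L) prev[j - 1L] else 0L
    pred <- switch(as.character(ft),
                   "1" = left,
                   "3" = floor((left + up) / 2),
                   "4" = paeth(left, up, ul),
                   stopf("unknown PNG filter type %d", ft))
    out[j] <- (cur[j] + pred) %% 256L
  }
  out
}
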