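# Minimal pure-R PNG codec.
#
# No PNG-reading package ships with the runtime, so the container format is
# implemented here directly. DEFLATE is delegated to base R: memCompress()
# with type "gzip" emits and memDecompress() accepts raw zlib streams
# (RFC 1950), which is exactly what PNG's IDAT carries. Supported: bit
# depths 8/16, colour types 0 (gray), 2 (RGB), 4 (gray+alpha) and 6 (RGBA)
# on read (alpha dropped); writing uses filter 0 (None); no interlacing,
# no palettes.

.png_signature <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

.crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  tab <- integer(256)
  for (k in 0:255) {
    c <- k
    for (i in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[k + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v) {
    crc <- bitwXor(.crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

int_to_be4 <- function(x) {
  # x: non-negative double < 2^32 (or signed int reinterpreted as unsigned)
  u <- as.numeric(x)
  if (u < 0) u <- u + 4294967296
  as.raw(c(floor(u / 16777216) %% 256, floor(u / 65536) %% 256,
           floor(u / 256) %% 256, u %% 256))
}

be4_to_num <- function(r) {
  v <- as.integer(r)
  ((v[1] * 256 + v[2]) * 256 + v[3]) * 256 + v[4]
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_be4(length(data)), body, int_to_be4(crc32(body)))
}

#' Write a PNG file (pure R)
#'
#' @param pixels integer array `H x W x C` (C = 1 or 3) or matrix `H x W`,
#'   values in `[0, 2^bit_depth - 1]`.
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @keywords internal
write_png <- function(pixels, path, bit_depth = 8L) {
  abort_if(!bit_depth %in% c(8L, 16L), "write_png: bit_depth must be 8 or 16")
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  d <- dim(pixels)
  abort_if(length(d) != 3L || !d[3] %in% c(1L, 3L),
           "write_png: pixels must be H x W x C with C in {1, 3}")
  h <- d[1]; w <- d[2]; ch <- d[3]
  maxv <- 2^bit_depth - 1
  v <- round(as.numeric(pixels))
  abort_if(any(!is.finite(v)) || any(v < 0) || any(v > maxv),
           "write_png: pixel values out of range for bit depth")

  color_type <- if (ch == 1L) 0L else 2L
  # interleave channels pixel-major, rows top to bottom
  # build a (w*ch) x h matrix of sample values in scanline order
  samp <- aperm(array(v, c(h, w, ch)), c(3, 2, 1))  # ch x w x h
  dim(samp) <- c(ch * w, h)
  if (bit_depth == 8L) {
    bytes <- matrix(as.raw(samp), nrow = ch * w)
  } else {
    hi <- as.raw(samp %/% 256)
    lo <- as.raw(samp %% 256)
    bytes <- matrix(raw(2L * ch * w * h), nrow = 2L * ch * w)
    bytes[seq(1L, 2L * ch * w, by = 2L), ] <- matrix(hi, nrow = ch * w)
    bytes[seq(2L, 2L * ch * w, by = 2L), ] <- matrix(lo, nrow = ch * w)
  }
  scan <- rbind(matrix(as.raw(0L), 1L, h), bytes)  # filter byte 0 per row
  zdata <- memCompress(as.raw(scan), type = "gzip")

  ihdr <- c(int_to_be4(w), int_to_be4(h), as.raw(bit_depth),
            as.raw(color_type), as.raw(0L), as.raw(0L), as.raw(0L))
  out <- c(.png_signature,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zdata),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# reconstructs one scanline given filter type; all args integer vectors
.png_unfilter_row <- function(ftype, raw_row, prev, bpp) {
  n <- length(raw_row)
  if (ftype == 0L) return(raw_row)
  if (ftype == 2L) return((raw_row + prev) %% 256L)
  npix <- n %/% bpp
  m <- matrix(raw_row, nrow = bpp)
  pm <- matrix(prev, nrow = bpp)
  if (ftype == 1L) {          # Sub
    for (j in 2:npix) m[, j] <- (m[, j] + m[, j - 1L]) %% 256L
    return(as.integer(m))
  }
  if (ftype == 3L) {          # Average
    m[, 1L] <- (m[, 1L] + pm[, 1L] %/% 2L) %% 256L
    if (npix > 1L) for (j in 2:npix) {
      m[, j] <- (m[, j] + (m[, j - 1L] + pm[, j]) %/% 2L) %% 256L
    }
    return(as.integer(m))
  }
  if (ftype == 4L) {          # Paeth
    left <- integer(bpp); upleft <- integer(bpp)
    for (j in 1:npix) {
      up <- pm[, j]
      p <- left + up - upleft
      pa <- abs(p - left); pb <- abs(p - up); pc <- abs(p - upleft)
      pred <- ifelse(pa <= pb & pa <= pc, left, ifelse(pb <= pc, up, upleft))
      m[, j] <- (m[, j] + pred) %% 256L
      upleft <- up
      left <- m[, j]
    }
    return(as.integer(m))
  }
  abort_if(TRUE, "read_png: unsupported scanline filter ", ftype)
}

#' Read a PNG file (pure R)
#'
#' @param path input path.
#' @return list with `pixels` (integer array H x W x C, alpha dropped),
#'   `bit_depth` (8 or 16).
#' @keywords internal
read_png <- function(path) {
  abort_if(!file.exists(path), "cannot read PNG: no such file: ", path,
           class = "pictodepth_io_error")
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  buf <- readBin(con, "raw", n = sz)
  abort_if(length(buf) < 8L || !identical(buf[1:8], .png_signature),
           "not a PNG file: ", path, class = "pictodepth_io_error")
  pos <- 9L
  ihdr <- NULL
  idat <- list()
  while (pos + 8L <= length(buf)) {
    len <- be4_to_num(buf[pos:(pos + 3L)])
    type <- rawToChar(buf[(pos + 4L):(pos + 7L)])
    data_start <- pos + 8L
    data <- if (len > 0) buf[data_start:(data_start + len - 1L)] else raw(0)
    if (type == "IHDR") ihdr <- data
    if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    if (type == "IEND") break
    pos <- data_start + len + 4L
  }
  abort_if(is.null(ihdr), "corrupt PNG (no IHDR): ", path,
           class = "pictodepth_io_error")
  w <- be4_to_num(ihdr[1:4]); h <- be4_to_num(ihdr[5:8])
  abort_if(w < 1 || h < 1, "zero-size PNG image: ", path)
  bit_depth <- as.integer(ihdr[9])
  color_type <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  abort_if(interlace != 0L, "interlaced PNG not supported: ", path)
  abort_if(!bit_depth %in% c(8L, 16L),
           "only 8/16-bit PNG supported (got depth ", bit_depth, "): ", path)
  nch <- switch(as.character(color_type),
                "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
                abort_if(TRUE, "unsupported PNG colour type ", color_type))
  bps <- bit_depth %/% 8L
  bpp <- nch * bps
  rowbytes <- w * bpp

  z <- do.call(c, idat)
  dec <- memDecompress(z, type = "gzip")
  abort_if(length(dec) != h * (rowbytes + 1L),
           "corrupt PNG pixel data: ", path, class = "pictodepth_io_error")
  dm <- matrix(as.integer(dec), nrow = rowbytes + 1L)
  filters <- dm[1L, ]
  out <- matrix(0L, rowbytes, h)
  prev <- integer(rowbytes)
  for (r in seq_len(h)) {
    prev <- .png_unfilter_row(filters[r], dm[-1L, r], prev, bpp)
    out[, r] <- prev
  }
  if (bps == 2L) {
    vals <- out[seq(1L, rowbytes, by = 2L), , drop = FALSE] * 256L +
      out[seq(2L, rowbytes, by = 2L), , drop = FALSE]
  } else {
    vals <- out
  }
  # vals: (w*nch) x h sample-major; reshape to H x W x nch
  arr <- aperm(array(vals, c(nch, w, h)), c(3, 2, 1))
  if (nch == 2L) arr <- arr[, , 1L, drop = FALSE]
  if (nch == 4L) arr <- arr[, , 1:3, drop = FALSE]
  list(pixels = arr, bit_depth = bit_depth)
}
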