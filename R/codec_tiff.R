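# Minimal pure-R baseline TIFF codec: uncompressed, chunky planar layout,
# little-endian on write, both byte orders on read. Sample formats: uint8,
# uint16 and float32 (the float path serializes ground-truth height and
# normal fields losslessly).

.tiff_tag <- function(id, type, count, value_or_offset) {
  # returns a raw(12) little-endian IFD entry; value_or_offset already
  # packed into 4 bytes when inline
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_or_offset)
}

.le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.le2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2, endian = "little"),
                         raw(2))

#' Write a TIFF file (pure R, uncompressed)
#'
#' @param pixels `H x W x C` array (C = 1 or 3) or `H x W` matrix. For
#'   integer sample formats values must lie in `[0, 2^bit_depth - 1]`;
#'   for `sample_format = "float"` any finite numeric is stored as float32.
#' @param path output path.
#' @param bit_depth 8 or 16 (ignored for float, which is 32).
#' @param sample_format `"uint"` or `"float"`.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff <- function(pixels, path, bit_depth = 8L,
                       sample_format = c("uint", "float")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  d <- dim(pixels)
  abort_if(length(d) != 3L || !d[3] %in% c(1L, 3L),
           "write_tiff: pixels must be H x W x C with C in {1, 3}")
  h <- d[1]; w <- d[2]; ch <- d[3]
  abort_if(any(!is.finite(pixels)), "write_tiff: non-finite pixel values")

  if (sample_format == "float") {
    bit_depth <- 32L
    fmt_code <- 3L
  } else {
    abort_if(!bit_depth %in% c(8L, 16L), "write_tiff: bit_depth must be 8 or 16")
    fmt_code <- 1L
    maxv <- 2^bit_depth - 1
    abort_if(any(pixels < 0) || any(pixels > maxv),
             "write_tiff: pixel values out of range for bit depth")
  }
  bps <- bit_depth %/% 8L

  # sample order: pixel-interleaved, row-major rows top to bottom
  samp <- as.numeric(aperm(pixels, c(3, 2, 1)))  # ch fastest, then col, then row
  data <- if (sample_format == "float") {
    writeBin(samp, raw(), size = 4, endian = "little")
  } else if (bit_depth == 8L) {
    as.raw(round(samp))
  } else {
    writeBin(as.integer(round(samp)), raw(), size = 2, endian = "little")
  }

  header_len <- 8L
  data_offset <- header_len
  strip_bytes <- length(data)
  ifd_offset <- data_offset + strip_bytes
  # extra value area after the IFD for multi-valued tags when ch == 3
  n_tags <- 10L
  ifd_len <- 2L + 12L * n_tags + 4L
  extra_offset <- ifd_offset + ifd_len

  extra <- raw(0)
  if (ch == 3L) {
    bits_off <- extra_offset
    extra <- c(extra, writeBin(rep(as.integer(bit_depth), 3), raw(),
                               size = 2, endian = "little"))
    fmt_off <- extra_offset + length(extra)
    extra <- c(extra, writeBin(rep(fmt_code, 3L), raw(),
                               size = 2, endian = "little"))
    bits_val <- .le4(bits_off)
    fmt_val <- .le4(fmt_off)
    bits_count <- 3L; fmt_count <- 3L
  } else {
    bits_val <- .le2pad(bit_depth)
    fmt_val <- .le2pad(fmt_code)
    bits_count <- 1L; fmt_count <- 1L
  }
  photometric <- if (ch == 3L) 2L else 1L

  tags <- c(
    .tiff_tag(256, 4, 1, .le4(w)),              # ImageWidth (LONG)
    .tiff_tag(257, 4, 1, .le4(h)),              # ImageLength
    .tiff_tag(258, 3, bits_count, bits_val),    # BitsPerSample (SHORT)
    .tiff_tag(259, 3, 1, .le2pad(1)),           # Compression = none
    .tiff_tag(262, 3, 1, .le2pad(photometric)), # PhotometricInterpretation
    .tiff_tag(273, 4, 1, .le4(data_offset)),    # StripOffsets
    .tiff_tag(277, 3, 1, .le2pad(ch)),          # SamplesPerPixel
    .tiff_tag(278, 4, 1, .le4(h)),              # RowsPerStrip
    .tiff_tag(279, 4, 1, .le4(strip_bytes)),    # StripByteCounts
    .tiff_tag(339, 3, fmt_count, fmt_val)       # SampleFormat
  )
  ifd <- c(writeBin(n_tags, raw(), size = 2, endian = "little"),
           tags, .le4(0))

  out <- c(charToRaw("II"), writeBin(42L, raw(), size = 2, endian = "little"),
           .le4(ifd_offset), data, ifd, extra)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

.tiff_read_int <- function(buf, pos, size, endian) {
  v <- as.integer(buf[pos:(pos + size - 1L)])
  if (endian == "big") v <- rev(v)
  s <- 0
  for (k in seq_len(size)) s <- s + v[k] * 256^(k - 1)
  s
}

#' Read a TIFF file (pure R, uncompressed baseline)
#'
#' @param path input path.
#' @return list with `pixels` (numeric array H x W x C; integer-valued for
#'   uint formats, raw floats for float32), `bit_depth`, `sample_format`.
#' @keywords internal
read_tiff <- function(path) {
  abort_if(!file.exists(path), "cannot read TIFF: no such file: ", path,
           class = "pictodepth_io_error")
  con <- file(path, "rb")
  buf <- readBin(con, "raw", n = file.info(path)$size)
  close(con)
  order_tag <- rawToChar(buf[1:2])
  endian <- switch(order_tag, "II" = "little", "MM" = "big",
                   abort_if(TRUE, "not a TIFF file: ", path,
                            class = "pictodepth_io_error"))
  ifd_off <- .tiff_read_int(buf, 5L, 4L, endian)
  n_tags <- .tiff_read_int(buf, ifd_off + 1L, 2L, endian)
  tags <- list()
  for (k in seq_len(n_tags)) {
    base <- ifd_off + 3L + (k - 1L) * 12L
    id <- .tiff_read_int(buf, base, 2L, endian)
    type <- .tiff_read_int(buf, base + 2L, 2L, endian)
    count <- .tiff_read_int(buf, base + 4L, 4L, endian)
    tsize <- c(1, 1, 2, 4, 8)[type]
    inline <- count * tsize <= 4
    vals <- numeric(count)
    vpos <- if (inline) base + 8L else .tiff_read_int(buf, base + 8L, 4L, endian) + 1L
    for (m in seq_len(count)) {
      vals[m] <- .tiff_read_int(buf, vpos + (m - 1L) * tsize, tsize, endian)
    }
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      abort_if(is.null(default), "TIFF missing required tag ", id, ": ", path)
      return(default)
    }
    v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8)
  comp <- need(259, 1)
  abort_if(comp != 1, "compressed TIFF not supported: ", path)
  ch <- need(277, 1)
  fmt <- need(339, 1)[1]
  abort_if(length(unique(bits)) != 1, "mixed bits-per-sample TIFF unsupported")
  bit_depth <- bits[1]
  abort_if(!(bit_depth %in% c(8, 16) && fmt == 1) && !(bit_depth == 32 && fmt == 3),
           "unsupported TIFF sample layout (bits ", bit_depth, ", format ", fmt, ")")
  planar <- need(284, 1)
  abort_if(planar != 1, "planar TIFF not supported: ", path)
  offsets <- need(273)
  counts <- need(279, w * h * ch * bit_depth / 8)
  data <- do.call(c, lapply(seq_along(offsets), function(k) {
    buf[(offsets[k] + 1L):(offsets[k] + counts[k])]
  }))
  npix <- w * h * ch
  if (bit_depth == 32) {
    samp <- readBin(data, "numeric", n = npix, size = 4, endian = endian)
  } else if (bit_depth == 16) {
    samp <- readBin(data, "integer", n = npix, size = 2, signed = FALSE,
                    endian = endian)
  } else {
    samp <- as.integer(data[seq_len(npix)])
  }
  arr <- aperm(array(as.numeric(samp), c(ch, w, h)), c(3, 2, 1))
  list(pixels = arr, bit_depth = as.integer(bit_depth),
       sample_format = if (fmt == 3) "float" else "uint")
}
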