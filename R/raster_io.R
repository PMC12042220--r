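#' Radiance image container
#'
#' Wraps an `H x W x C` array of linear-scale intensities in `[0, 1]`
#' (C = 3 colour or C = 1 grayscale). This is the observed image `I` of the
#' image formation model `I = R x S`. Reconstruction needs local
#' neighbourhoods, so images smaller than 8 x 8 are rejected.
#'
#' @param pixels numeric array `H x W x C` or matrix `H x W`.
#' @return an object of class `radiance_image` with fields `pixels`,
#'   `height_px`, `width_px`, `channels`.
#' @export
radiance_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  d <- dim(pixels)
  abort_if(length(d) != 3L || !d[3] %in% c(1L, 3L),
           "radiance_image: pixels must be H x W x C with C in {1, 3}")
  abort_if(d[1] < 8L || d[2] < 8L,
           "radiance_image: image must be at least 8 x 8, got ",
           d[1], " x ", d[2])
  abort_if(any(!is.finite(pixels)), "radiance_image: non-finite pixel values")
  abort_if(any(pixels < 0) || any(pixels > 1),
           "radiance_image: pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, height_px = d[1], width_px = d[2],
                 channels = d[3]),
            class = "radiance_image")
}

#' @export
print.radiance_image <- function(x, ...) {
  cat(sprintf("<radiance_image %d x %d, %d channel(s), range [%.4f, %.4f]>\n",
              x$height_px, x$width_px, x$channels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A binary raster delineating the object outline (e.g. a hand-drawn wing
#' outline); all reconstruction is restricted to its true set, which must be
#' non-empty and 4-connected.
#'
#' @param inside logical matrix.
#' @param repair if `TRUE`, keep only the largest 4-connected component
#'   (with a warning) instead of erroring on fragmented masks.
#' @return an object of class `region_mask` with field `inside`.
#' @export
region_mask <- function(inside, repair = FALSE) {
  abort_if(!is.matrix(inside) || !is.logical(inside),
           "region_mask: inside must be a logical matrix")
  abort_if(!any(inside), "region_mask: mask has no inside pixels")
  lab <- label_components4(inside)
  k <- max(lab)
  if (k > 1L) {
    abort_if(!repair, "region_mask: inside set has ", k,
             " 4-connected components; expected a single component")
    sizes <- tabulate(lab[inside], nbins = k)
    keep <- which.max(sizes)
    warning(sprintf(
      "mask has %d disconnected components; keeping the largest (%d px), dropping %d px",
      k, sizes[keep], sum(sizes) - sizes[keep]), call. = FALSE)
    inside <- lab == keep
  }
  structure(list(inside = inside), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask %d x %d, %d inside pixels>\n",
              nrow(x$inside), ncol(x$inside), sum(x$inside)))
  invisible(x)
}

#' sRGB transfer functions
#'
#' Standard sRGB electro-optical transfer and its inverse. Display-encoded
#' images must be linearized before any Lambertian shading analysis.
#'
#' @param x numeric values in `[0, 1]`.
#' @return transformed values in `[0, 1]`.
#' @export
srgb_to_linear <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_to_linear
#' @export
linear_to_srgb <- function(x) {
  ifelse(x <= 0.0031308, x * 12.92, 1.055 * x^(1 / 2.4) - 0.055)
}

.sniff_format <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 8L)
  close(con)
  if (length(magic) >= 8L && identical(magic, .png_signature)) return("png")
  if (length(magic) >= 2L) {
    tag <- rawToChar(magic[1:2])
    if (tag %in% c("II", "MM")) return("tiff")
    if (identical(magic[1:2], as.raw(c(0xff, 0xd8)))) return("jpeg")
  }
  "unknown"
}

#' Load an image file as a radiance image
#'
#' Reads a PNG or TIFF raster (8 or 16 bit), scales to `[0, 1]` (8-bit
#' divides by 255, 16-bit by 65535), drops any alpha channel, and by
#' default applies the sRGB-to-linear transfer so downstream shading math
#' operates on linear radiance. Float TIFF input is taken as already linear
#' in `[0, 1]`.
#'
#' JPEG is detected but not decodable in this pure-R build; convert to
#' PNG/TIFF first.
#'
#' @param path file path.
#' @param linearize_srgb apply the sRGB-to-linear transfer (default `TRUE`;
#'   set `FALSE` for data already in linear units, e.g. synthetic renders).
#' @param bit_depth_hint optional; checked against the file if supplied.
#' @return a [radiance_image].
#' @export
load_image <- function(path, linearize_srgb = TRUE, bit_depth_hint = NULL) {
  abort_if(!file.exists(path), "cannot read image: no such file: ", path,
           class = "pictodepth_io_error")
  fmt <- .sniff_format(path)
  abort_if(fmt == "jpeg",
           "JPEG decoding is not supported in this build; convert to PNG or TIFF: ",
           path, class = "pictodepth_io_error")
  abort_if(fmt == "unknown", "unrecognized image format: ", path,
           class = "pictodepth_io_error")
  r <- if (fmt == "png") read_png(path) else read_tiff(path)
  if (!is.null(bit_depth_hint)) {
    abort_if(r$bit_depth != bit_depth_hint,
             "bit depth mismatch: file is ", r$bit_depth, "-bit, hint was ",
             bit_depth_hint)
  }
  px <- r$pixels
  if (!is.null(r$sample_format) && identical(r$sample_format, "float")) {
    scaled <- px
  } else {
    scaled <- px / (2^r$bit_depth - 1)
  }
  if (linearize_srgb) scaled <- srgb_to_linear(scaled)
  radiance_image(scaled)
}

#' Write a `[0, 1]` raster to PNG or TIFF
#'
#' @param pixels numeric array/matrix with values in `[0, 1]`, or an
#'   integer-valued array already in `[0, 2^bit_depth - 1]` when
#'   `already_quantized = TRUE`.
#' @param path output path; format chosen by extension (.png, .tif, .tiff).
#' @param bit_depth 8 or 16.
#' @param already_quantized see `pixels`.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path, bit_depth = 8L,
                        already_quantized = FALSE) {
  if (inherits(pixels, "radiance_image")) pixels <- pixels$pixels
  q <- if (already_quantized) pixels else round(pixels * (2^bit_depth - 1))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    write_png(q, path, bit_depth = bit_depth)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff(q, path, bit_depth = bit_depth)
  } else {
    abort_if(TRUE, "write_image: unsupported extension .", ext)
  }
  invisible(path)
}

#' Load a region-of-interest mask
#'
#' Any nonzero pixel counts as inside. If the inside set has several
#' 4-connected components (stray pixels are common in hand-drawn masks),
#' the largest is kept and a warning is emitted.
#'
#' @param path single-channel PNG (or TIFF) mask file.
#' @param image the [radiance_image] the mask belongs to (shape check).
#' @return a [region_mask].
#' @export
load_mask <- function(path, image) {
  fmt <- .sniff_format(path)
  abort_if(fmt == "unknown", "unrecognized mask format: ", path,
           class = "pictodepth_io_error")
  r <- if (fmt == "png") read_png(path) else read_tiff(path)
  px <- r$pixels
  m <- px[, , 1] != 0
  if (dim(px)[3] > 1L) for (c in 2:dim(px)[3]) m <- m | (px[, , c] != 0)
  abort_if(nrow(m) != image$height_px || ncol(m) != image$width_px,
           "mask shape ", nrow(m), " x ", ncol(m),
           " does not match image ", image$height_px, " x ", image$width_px)
  abort_if(!any(m), "mask is empty (all zero): ", path)
  region_mask(m, repair = TRUE)
}

#' Log image
#'
#' Elementwise `log(max(pixel, eps_floor))`. Working in log colour-space
#' turns the multiplicative image formation model `I = R x S` into the
#' additive `log I = log R + log S`, so the decomposition solves a linear
#' problem in `log S`. The floor keeps black pixels bounded.
#'
#' @param image a [radiance_image].
#' @param eps_floor clamp value in `(0, 1)` applied before the log
#'   (default `1e-4`).
#' @return object of class `log_image` with `log_pixels` and `eps_floor`.
#' @export
to_log <- function(image, eps_floor = 1e-4) {
  abort_if(!is_scalar_num(eps_floor) || eps_floor <= 0 || eps_floor >= 1,
           "to_log: eps_floor must lie in (0, 1)")
  px <- if (inherits(image, "radiance_image")) image$pixels else image
  structure(list(log_pixels = log(pmax(px, eps_floor)), eps_floor = eps_floor),
            class = "log_image")
}

#' Encode a normal map as an 8-bit RGB raster
#'
#' RGB channels carry the x, y and z normal components: x and y are mapped
#' linearly from `[-1, 1]` to `[0, 255]`, z from `[0, 1]` to `[0, 255]`
#' (the usual tangent-space normal-map convention, e.g. flat-up
#' `(0, 0, 1)` becomes RGB `(128, 128, 255)`). Pixels outside the mask are
#' zeroed.
#'
#' @param normals `H x W x 3` array, unit vectors inside the mask.
#' @param mask a [region_mask].
#' @return integer array `H x W x 3` with values in `[0, 255]`.
#' @export
encode_normal_map <- function(normals, mask) {
  d <- dim(normals)
  abort_if(length(d) != 3L || d[3] != 3L,
           "encode_normal_map: normals must be H x W x 3")
  m <- mask$inside
  out <- array(0L, d)
  out[, , 1] <- round((normals[, , 1] + 1) / 2 * 255)
  out[, , 2] <- round((normals[, , 2] + 1) / 2 * 255)
  out[, , 3] <- round(pmax(normals[, , 3], 0) * 255)
  for (c in 1:3) {
    ch <- out[, , c]
    ch[!m] <- 0L
    out[, , c] <- ch
  }
  storage.mode(out) <- "integer"
  out
}

#' Decode an 8-bit RGB normal raster back to unit vectors
#'
#' Inverse of [encode_normal_map] up to 8-bit quantization.
#'
#' @param raster integer array `H x W x 3` in `[0, 255]`.
#' @return `H x W x 3` numeric array (not renormalized).
#' @export
decode_normal_map <- function(raster) {
  out <- array(0, dim(raster))
  out[, , 1] <- raster[, , 1] / 255 * 2 - 1
  out[, , 2] <- raster[, , 2] / 255 * 2 - 1
  out[, , 3] <- raster[, , 3] / 255
  out
}

#' Encode a height map as an 8-bit grayscale raster
#'
#' Min-max normalizes heights inside the mask to 0 (black, lowest /
#' furthest) .. 255 (white, highest / closest to the viewer). A constant
#' height field maps to uniform 128 (min = max leaves min-max scaling
#' undefined, so mid-gray is used by convention). Outside-mask pixels are 0.
#'
#' @param height numeric matrix `H x W`.
#' @param mask a [region_mask].
#' @return integer matrix with values in `[0, 255]`.
#' @export
encode_height_map <- function(height, mask) {
  abort_if(!is.matrix(height), "encode_height_map: height must be a matrix")
  m <- mask$inside
  abort_if(!all(dim(height) == dim(m)), "encode_height_map: shape mismatch")
  v <- height[m]
  abort_if(any(!is.finite(v)), "encode_height_map: non-finite heights inside mask")
  out <- matrix(0L, nrow(height), ncol(height))
  rng <- max(v) - min(v)
  if (rng == 0) {
    out[m] <- 128L
  } else {
    out[m] <- as.integer(round((height[m] - min(v)) / rng * 255))
  }
  out
}

#' Export a masked height field as an ASCII PLY mesh
#'
#' Builds a vertex grid over the inside-mask pixels (x = column, y = row,
#' z = height) and triangulates each 2 x 2 pixel quad whose corners are
#' inside the mask (two triangles for full quads, one for 3-corner quads).
#'
#' @param height numeric matrix.
#' @param mask a [region_mask].
#' @param path output `.ply` path.
#' @param z_scale multiplier applied to heights (default 1).
#' @return `path`, invisibly.
#' @export
write_ply <- function(height, mask, path, z_scale = 1) {
  m <- mask$inside
  h <- nrow(m); w <- ncol(m)
  idx <- matrix(NA_integer_, h, w)
  inside_lin <- which(m)
  idx[inside_lin] <- seq_along(inside_lin) - 1L  # 0-based vertex ids
  rows <- ((inside_lin - 1L) %% h) + 1L
  cols <- ((inside_lin - 1L) %/% h) + 1L
  verts <- sprintf("%d %d %.6g", cols - 1L, rows - 1L,
                   height[inside_lin] * z_scale)

  faces <- character(0)
  if (h > 1L && w > 1L) {
    a <- idx[-h, -w]; b <- idx[-h, -1]; c_ <- idx[-1, -w]; d <- idx[-1, -1]
    quad <- cbind(as.vector(a), as.vector(b), as.vector(c_), as.vector(d))
    nin <- rowSums(!is.na(quad))
    full <- quad[nin == 4L, , drop = FALSE]
    tri3 <- quad[nin == 3L, , drop = FALSE]
    if (nrow(full)) {
      faces <- c(faces,
                 sprintf("3 %d %d %d", full[, 1], full[, 3], full[, 2]),
                 sprintf("3 %d %d %d", full[, 2], full[, 3], full[, 4]))
    }
    if (nrow(tri3)) {
      tri <- t(apply(tri3, 1, function(r) r[!is.na(r)]))
      faces <- c(faces, sprintf("3 %d %d %d", tri[, 1], tri[, 3], tri[, 2]))
    }
  }
  lines <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", length(verts)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", length(faces)),
    "property list uchar int vertex_indices",
    "end_header", verts, faces)
  writeLines(lines, path)
  invisible(path)
}
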