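# Synthetic Lambertian scenes with known ground truth. These stand in for
# the photographs the pipeline is meant for (curled leaves, bark, patterned
# moth wings) and give every stage an exact oracle: the true height field,
# the true normals derived from it, the true reflectance and the light.

#' Generate a ground-truth height field
#'
#' Kinds (x = column index 0-based, y = row index 0-based, heights in
#' pixel units):
#' * `flat`: all zeros;
#' * `tilted_plane`: `sx*x + sy*y` (params `sx`, `sy`, default 1, 0);
#' * `hemisphere`: spherical cap of radius `r` (default `min(size)/3`)
#'   centred in the image, 0 outside the cap;
#' * `curled_sheet`: flat sheet whose far edge curls smoothly upward like
#'   a drying leaf — cylindrical along y, height
#'   `amplitude * (1 - cos(pi*u))/2` where `u` ramps 0..1 over the curled
#'   fraction of the width (params `amplitude` default `size[2]/8`,
#'   `start_frac` default 0.5);
#' * `gabor_bumps`: sum of `n` seeded random oriented Gaussian-envelope
#'   cosine bumps (bark-like relief; params `n` default 8, `amp` default 3,
#'   `sigma_range` default `c(4, 12)`).
#'
#' @param kind one of `"flat"`, `"tilted_plane"`, `"hemisphere"`,
#'   `"curled_sheet"`, `"gabor_bumps"`.
#' @param size `c(H, W)`, each at least 16.
#' @param params named list of kind-specific parameters.
#' @param seed integer seed (used by `gabor_bumps`).
#' @return `H x W` numeric matrix.
#' @export
make_height_field <- function(kind, size, params = list(), seed = 1L) {
  abort_if(length(size) != 2L || any(size < 16L),
           "make_height_field: size must be c(H, W) with both >= 16")
  h <- size[1]; w <- size[2]
  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), w), h, w)
  switch(kind,
    flat = matrix(0, h, w),
    tilted_plane = {
      p <- modifyList(list(sx = 1, sy = 0), params)
      p$sx * x + p$sy * y
    },
    hemisphere = {
      p <- modifyList(list(r = min(h, w) / 3), params)
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      d2 <- (x - cx)^2 + (y - cy)^2
      sqrt(pmax(p$r^2 - d2, 0))
    },
    curled_sheet = {
      p <- modifyList(list(amplitude = w / 8, start_frac = 0.5), params)
      u <- pmin(pmax((x / (w - 1) - p$start_frac) / (1 - p$start_frac), 0), 1)
      p$amplitude * (1 - cos(pi * u)) / 2
    },
    gabor_bumps = {
      p <- modifyList(list(n = 8L, amp = 3, sigma_range = c(4, 12)), params)
      with_seed(seed, {
        H <- matrix(0, h, w)
        for (k in seq_len(p$n)) {
          cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1)
          sg <- runif(1, p$sigma_range[1], p$sigma_range[2])
          th <- runif(1, 0, pi)
          lam <- runif(1, 2 * sg, 4 * sg)
          a <- runif(1, -p$amp, p$amp)
          xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
          env <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sg^2))
          H <- H + a * env * cos(2 * pi * xr / lam)
        }
        H
      })
    },
    abort_if(TRUE, "make_height_field: unknown kind '", kind, "'")
  )
}

#' Generate a ground-truth reflectance pattern
#'
#' Kinds (values confined to `[0.05, 1]`, strictly positive for log
#' space):
#' * `uniform`: constant `value` (default 0.5);
#' * `mondrian`: Voronoi tessellation of `n_patches` seeded random sites
#'   (default 6); patch albedos are distinct geometric levels spanning
#'   `value_range` (default `c(0.1, 0.9)`), so every pair of patches has
#'   log-contrast at least `log(max/min)/(n_patches - 1)`;
#' * `spots`: `n` discs (default 5) of albedo `fg` (default 0.15) on `bg`
#'   (default 0.7), seeded random centres/radii;
#' * `stripes`: square-wave stripes of period `period` px (default 16) at
#'   angle `theta` (default 0) alternating `values` (default 0.2/0.8);
#' * `eyespot`: concentric rings around the centre with radii `radii` and
#'   albedos `values` (defaults emulate a dark-pupil pale-iris eyespot on
#'   a mid background).
#'
#' @param kind pattern kind.
#' @param size `c(H, W)`.
#' @param params named list of kind-specific parameters; `channels`
#'   (default 3) sets C.
#' @param seed integer seed for random placements.
#' @return `H x W x C` numeric array in `[0.05, 1]`.
#' @export
make_reflectance <- function(kind, size, params = list(), seed = 1L) {
  h <- size[1]; w <- size[2]
  nc <- if (!is.null(params$channels)) as.integer(params$channels) else 3L
  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), w), h, w)
  plane <- switch(kind,
    uniform = {
      p <- modifyList(list(value = 0.5), params)
      abort_if(p$value < 0.05 || p$value > 1,
               "make_reflectance: value outside [0.05, 1]")
      matrix(p$value, h, w)
    },
    mondrian = {
      p <- modifyList(list(n_patches = 6L, value_range = c(0.1, 0.9)), params)
      abort_if(p$value_range[1] < 0.05 || p$value_range[2] > 1,
               "make_reflectance: value_range outside [0.05, 1]")
      with_seed(seed, {
        sx <- runif(p$n_patches, 0, w - 1)
        sy <- runif(p$n_patches, 0, h - 1)
        levels <- exp(seq(log(p$value_range[1]), log(p$value_range[2]),
                          length.out = p$n_patches))
        levels <- sample(levels)
        lab <- matrix(0L, h, w)
        best <- matrix(Inf, h, w)
        for (k in seq_len(p$n_patches)) {
          d2 <- (x - sx[k])^2 + (y - sy[k])^2
          upd <- d2 < best
          lab[upd] <- k
          best[upd] <- d2[upd]
        }
        matrix(levels[lab], h, w)
      })
    },
    spots = {
      p <- modifyList(list(n = 5L, fg = 0.15, bg = 0.7,
                           radius_range = c(3, max(4, min(h, w) / 8))),
                      params)
      with_seed(seed, {
        out <- matrix(p$bg, h, w)
        placed <- 0L
        tries <- 0L
        centers <- matrix(numeric(0), 0, 3)
        while (placed < p$n && tries < 1000L) {
          tries <- tries + 1L
          r <- runif(1, p$radius_range[1], p$radius_range[2])
          cx <- runif(1, r, w - 1 - r); cy <- runif(1, r, h - 1 - r)
          if (nrow(centers) &&
              any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
                  (centers[, 3] + r + 2)^2)) next
          out[(x - cx)^2 + (y - cy)^2 <= r^2] <- p$fg
          centers <- rbind(centers, c(cx, cy, r))
          placed <- placed + 1L
        }
        abort_if(placed < p$n,
                 "make_reflectance: could not place ", p$n, " disjoint spots")
        out
      })
    },
    stripes = {
      p <- modifyList(list(period = 16, theta = 0, values = c(0.2, 0.8)),
                      params)
      u <- x * cos(p$theta) + y * sin(p$theta)
      phase <- floor(u / (p$period / 2)) %% 2
      matrix(ifelse(phase == 0, p$values[1], p$values[2]), h, w)
    },
    eyespot = {
      p <- modifyList(list(radii = c(6, 12, 18),
                           values = c(0.08, 0.85, 0.3),
                           bg = 0.55), params)
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      d <- sqrt((x - cx)^2 + (y - cy)^2)
      out <- matrix(p$bg, h, w)
      for (k in rev(seq_along(p$radii))) out[d <= p$radii[k]] <- p$values[k]
      out
    },
    abort_if(TRUE, "make_reflectance: unknown kind '", kind, "'")
  )
  abort_if(any(plane < 0.05 - 1e-12) || any(plane > 1 + 1e-12),
           "make_reflectance: pattern left the valid range [0.05, 1]")
  array(rep(plane, nc), c(h, w, nc))
}

#' Normals of a height field (forward differences)
#'
#' `N = normalize(-dH/dx, -dH/dy, 1)` with forward differences, the exact
#' discrete inverse of the gradient rule `grad H = -(Nx/Nz, Ny/Nz)`.
#'
#' @param height `H x W` matrix.
#' @return `H x W x 3` unit-normal array.
#' @export
height_to_normals <- function(height) {
  g <- grad_forward(height)
  nrm <- sqrt(g$gx^2 + g$gy^2 + 1)
  out <- array(0, c(nrow(height), ncol(height), 3))
  out[, , 1] <- -g$gx / nrm
  out[, , 2] <- -g$gy / nrm
  out[, , 3] <- 1 / nrm
  out
}

#' Wing-shaped region mask
#'
#' Two mirrored half-ellipses joined at the vertical midline, a
#' non-rectangular stand-in for a hand-drawn wing outline.
#'
#' @param size `c(H, W)`.
#' @param margin_frac border margin as a fraction of size (default 0.08).
#' @return a [region_mask].
#' @export
wing_mask <- function(size, margin_frac = 0.08) {
  h <- size[1]; w <- size[2]
  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), w), h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  ax <- (w / 2) * (1 - margin_frac)
  top <- cy * (1 - margin_frac)
  bot <- (h - 1 - cy) * (1 - 2 * margin_frac)
  ell <- ((x - cx) / ax)^2 +
    ifelse(y <= cy, ((y - cy) / top)^2, ((y - cy) / bot)^2)
  region_mask(ell <= 1)
}

#' Render a Lambertian scene with ground truth
#'
#' Forward model: normals from the height field, shading
#' `max(0, <D, N>) + ambient`, image `clip(R * shading, 0, 1)`, optional
#' i.i.d. Gaussian pixel noise. The returned bundle carries all ground
#' truth and asserts its own consistency invariants at creation:
#' the normal/height roundtrip (forward-difference residual below 1e-10)
#' and the rendering equation (exact on the noiseless render).
#'
#' @param height `H x W` true height field.
#' @param reflectance `H x W x C` true reflectance in `(0, 1]`.
#' @param light a [light_direction].
#' @param ambient ambient illumination in `[0, 1)` added to the direct
#'   term (default 0.1 so black shadow pixels stay off the log floor; the
#'   pure Lambertian model has no ambient term — set 0 to disable).
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (default 0; applied after clipping, then re-clipped).
#' @param mask optional [region_mask] (default: all pixels).
#' @param seed integer seed (noise).
#' @return a `synthetic_scene`: list with `true_height`,
#'   `true_reflectance`, `true_normals`, `light`, `ambient`, `rendered`
#'   (a [radiance_image]), `mask`, `noise_sd`, `seed`.
#' @export
render_scene <- function(height, reflectance, light, ambient = 0.1,
                         noise_sd = 0, mask = NULL, seed = 1L) {
  h <- nrow(height); w <- ncol(height)
  if (is.matrix(reflectance)) reflectance <- array(reflectance, c(h, w, 1L))
  abort_if(!all(dim(reflectance)[1:2] == c(h, w)),
           "render_scene: height/reflectance shape mismatch")
  abort_if(ambient < 0 || ambient >= 1, "render_scene: ambient must be in [0, 1)")
  normals <- height_to_normals(height)
  D <- light$vector
  lam <- D[1] * normals[, , 1] + D[2] * normals[, , 2] + D[3] * normals[, , 3]
  shading <- pmax(lam, 0) + ambient
  nc <- dim(reflectance)[3]
  img <- array(0, c(h, w, nc))
  for (c in seq_len(nc)) {
    img[, , c] <- pmin(pmax(reflectance[, , c] * shading, 0), 1)
  }
  clean <- img
  if (noise_sd > 0) {
    img <- with_seed(seed, img + array(rnorm(length(img), 0, noise_sd), dim(img)))
    img <- pmin(pmax(img, 0), 1)
  }
  if (is.null(mask)) mask <- region_mask(matrix(TRUE, h, w))

  # invariant 1: normals round-trip to the forward-difference gradient
  g_true <- grad_forward(height)
  g_back <- list(gx = -normals[, , 1] / normals[, , 3],
                 gy = -normals[, , 2] / normals[, , 3])
  abort_if(max(abs(g_back$gx - g_true$gx), abs(g_back$gy - g_true$gy)) > 1e-10,
           "render_scene: normal/height roundtrip invariant violated")
  # invariant 2: rendering equation holds on the noiseless image
  chk <- array(0, c(h, w, nc))
  for (c in seq_len(nc)) {
    chk[, , c] <- pmin(pmax(reflectance[, , c] * (pmax(lam, 0) + ambient), 0), 1)
  }
  abort_if(max(abs(chk - clean)) > 0,
           "render_scene: rendering invariant violated")

  structure(list(true_height = height, true_reflectance = reflectance,
                 true_normals = normals, light = light, ambient = ambient,
                 rendered = radiance_image(img), mask = mask,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d, height range [%.3g, %.3g], ambient %.2f, noise sd %.3g>\n",
              nrow(x$true_height), ncol(x$true_height),
              min(x$true_height), max(x$true_height), x$ambient, x$noise_sd))
  invisible(x)
}

#' Serialize a synthetic scene to a directory
#'
#' Writes `rendered.png` (16-bit, linear values), `mask.png`,
#' `true_height.tif` and `true_normals.tif` (32-bit float TIFF) and a
#' `metadata.json` sidecar recording light, ambient, noise and seed.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(scene$rendered$pixels, file.path(dir, "rendered.png"),
              bit_depth = 16L)
  write_image(scene$mask$inside * 1, file.path(dir, "mask.png"), bit_depth = 8L)
  write_tiff(scene$true_height, file.path(dir, "true_height.tif"),
             sample_format = "float")
  write_tiff(scene$true_normals, file.path(dir, "true_normals.tif"),
             sample_format = "float")
  meta <- list(azimuth_rad = scene$light$azimuth_rad,
               elevation_rad = scene$light$elevation_rad,
               ambient = scene$ambient, noise_sd = scene$noise_sd,
               seed = scene$seed, encoding = "linear")
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a serialized synthetic scene
#'
#' @param dir directory written by [save_scene].
#' @return a `synthetic_scene` (reconstructed; 16-bit quantization applies
#'   to the rendered image).
#' @export
load_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  img <- load_image(file.path(dir, "rendered.png"), linearize_srgb = FALSE)
  mask_arr <- read_png(file.path(dir, "mask.png"))$pixels
  mask <- region_mask(mask_arr[, , 1] != 0, repair = TRUE)
  th <- read_tiff(file.path(dir, "true_height.tif"))$pixels[, , 1]
  tn <- read_tiff(file.path(dir, "true_normals.tif"))$pixels
  structure(list(true_height = th,
                 true_reflectance = NULL,
                 true_normals = tn,
                 light = light_direction(meta$azimuth_rad, meta$elevation_rad),
                 ambient = meta$ambient, rendered = img, mask = mask,
                 noise_sd = meta$noise_sd, seed = meta$seed),
            class = "synthetic_scene")
}
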