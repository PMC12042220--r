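#' Pipeline configuration
#'
#' Bundles the per-stage configurations plus global options. Round-trips
#' losslessly through JSON ([write_pipeline_config] /
#' [read_pipeline_config]).
#'
#' @param decomposition a [decomposition_config].
#' @param normals a [normal_config].
#' @param eps_floor log clamp for black pixels (default 1e-4).
#' @param ambient_free if `TRUE`, no ambient handling is assumed anywhere
#'   (informational; the closed-form model itself has no ambient term).
#' @param linearize_srgb apply sRGB linearization when loading images
#'   (default `TRUE`; photographs are display-encoded, synthetic renders
#'   are linear).
#' @param seed integer seed forwarded to any stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(decomposition = decomposition_config(),
                            normals = normal_config(),
                            eps_floor = 1e-4,
                            ambient_free = TRUE,
                            linearize_srgb = TRUE,
                            seed = 1L) {
  structure(list(decomposition = decomposition, normals = normals,
                 eps_floor = eps_floor, ambient_free = ambient_free,
                 linearize_srgb = linearize_srgb, seed = as.integer(seed)),
            class = "pipeline_config")
}

# recursively drop S3 classes so jsonlite serializes plain lists
.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(.strip_classes(config), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dc <- do.call(decomposition_config, raw$decomposition)
  nc_args <- raw$normals
  if (!is.null(nc_args$edge_threshold_c) && !length(nc_args$edge_threshold_c)) {
    nc_args$edge_threshold_c <- NULL
  }
  nc <- do.call(normal_config, nc_args)
  pipeline_config(decomposition = dc, normals = nc,
                  eps_floor = raw$eps_floor,
                  ambient_free = isTRUE(raw$ambient_free),
                  linearize_srgb = isTRUE(raw$linearize_srgb),
                  seed = raw$seed)
}

#' Run the three-stage reconstruction on in-memory inputs
#'
#' Stage (i) decomposes the image into shading and reflectance, stage
#' (ii) estimates the light direction and the normal map, stage (iii)
#' converts normals to a height gradient, integrates it over the ROI with
#' a zero border anchor, and removes the best-fit plane. All stage
#' residuals and timings are collected.
#'
#' @param image a [radiance_image].
#' @param mask a [region_mask].
#' @param config a [pipeline_config].
#' @return a `pipeline_result`: list with `reflectance`, `shading`,
#'   `normals`, `light`, `height` (detrended [height_map]),
#'   `height_raw` (before detrending), `stages` (per-stage diagnostics
#'   and runtimes in seconds).
#' @export
reconstruct_depth <- function(image, mask, config = pipeline_config()) {
  stages <- list()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  dec <- decompose(image, mask, config$decomposition,
                   eps_floor = config$eps_floor)
  stages$decompose <- c(dec$diagnostics, list(seconds = tic() - t0))

  t0 <- tic()
  light <- estimate_light_direction(dec$shading, mask)
  nrm <- estimate_normals(dec$shading, dec$reflectance, light, mask,
                          config$normals)
  stages$normals <- c(nrm$diagnostics,
                      list(azimuth_rad = light$azimuth_rad,
                           seconds = tic() - t0))

  t0 <- tic()
  grad <- normals_to_gradient(nrm$normals, mask)
  hm_raw <- integrate_height(grad, mask)
  hm <- detrend_plane(hm_raw, mask)
  stages$height <- c(hm_raw$diagnostics,
                     list(anchor_index = hm_raw$anchor_index,
                          seconds = tic() - t0))

  structure(list(reflectance = dec$reflectance, shading = dec$shading,
                 normals = nrm$normals, light = light,
                 height = hm, height_raw = hm_raw, stages = stages),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  light azimuth: %.1f deg\n", x$light$azimuth_rad * 180 / pi))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %6.2fs  residual %.3g\n", s, st$seconds,
                if (!is.null(st$relative_residual)) st$relative_residual else NA))
  }
  invisible(x)
}

#' Run the full pipeline on image files and write all artifacts
#'
#' Output directory receives the panel rasters `R.png`, `S.png`, `N.png`,
#' `H.png`, the float height `H.tif`, optionally `mesh.ply`, and a
#' `report.json` with config, input hashes, seed, light direction and
#' per-stage residuals/timings — enough to reproduce the run exactly.
#'
#' @param image_path input photograph (PNG/TIFF).
#' @param mask_path ROI mask raster (any nonzero pixel = inside).
#' @param config a [pipeline_config].
#' @param out_dir output directory (created).
#' @param export_mesh also write an ASCII PLY mesh of the height field.
#' @return the `pipeline_result`, invisibly.
#' @export
run_pipeline <- function(image_path, mask_path, config = pipeline_config(),
                         out_dir = "pictodepth_out", export_mesh = FALSE) {
  image <- load_image(image_path, linearize_srgb = config$linearize_srgb)
  mask <- load_mask(mask_path, image)
  res <- reconstruct_depth(image, mask, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  refl_out <- pmin(pmax(res$reflectance, 0), 1)
  write_image(refl_out, file.path(out_dir, "R.png"))
  shade_out <- res$shading / max(res$shading[mask$inside])
  shade_out[!mask$inside] <- 0
  write_image(pmin(pmax(shade_out, 0), 1), file.path(out_dir, "S.png"))
  write_image(encode_normal_map(res$normals, mask), file.path(out_dir, "N.png"),
              already_quantized = TRUE)
  write_image(encode_height_map(res$height$values, mask),
              file.path(out_dir, "H.png"), already_quantized = TRUE)
  write_tiff(res$height$values, file.path(out_dir, "H.tif"),
             sample_format = "float")
  if (export_mesh) {
    write_ply(res$height$values, mask, file.path(out_dir, "mesh.ply"))
  }

  report <- list(
    config = .strip_classes(config),
    inputs = list(
      image = image_path, image_md5 = unname(tools::md5sum(image_path)),
      mask = mask_path, mask_md5 = unname(tools::md5sum(mask_path))),
    seed = config$seed,
    light = list(azimuth_rad = res$light$azimuth_rad,
                 elevation_rad = res$light$elevation_rad,
                 vector = res$light$vector),
    stages = res$stages)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}

# ---- scene recipe registry ---------------------------------------------

.recipes <- list(
  curled_leaf_like = function(seed) {
    size <- c(128L, 128L)
    height <- make_height_field("curled_sheet", size,
                                list(amplitude = 16, start_frac = 0.45))
    refl <- make_reflectance("uniform", size, list(value = 0.7))
    render_scene(height, refl, light_direction(0), ambient = 0.1,
                 mask = wing_mask(size), seed = seed)
  },
  flat_mondrian = function(seed) {
    size <- c(128L, 128L)
    height <- make_height_field("flat", size)
    refl <- make_reflectance("mondrian", size, list(n_patches = 6L),
                             seed = seed)
    render_scene(height, refl, light_direction(0), ambient = 0.1, seed = seed)
  },
  hemisphere_uniform = function(seed) {
    size <- c(64L, 64L)
    r <- 21
    height <- make_height_field("hemisphere", size, list(r = r))
    refl <- make_reflectance("uniform", size, list(value = 0.7))
    x <- matrix(rep(0:(size[2] - 1L), each = size[1]), size[1], size[2])
    y <- matrix(rep(0:(size[1] - 1L), size[2]), size[1], size[2])
    cap <- (x - (size[2] - 1) / 2)^2 + (y - (size[1] - 1) / 2)^2 <= (r - 1)^2
    render_scene(height, refl, light_direction(pi / 6), ambient = 0.1,
                 mask = region_mask(cap), seed = seed)
  },
  bark_bumps = function(seed) {
    size <- c(96L, 96L)
    height <- make_height_field("gabor_bumps", size,
                                list(n = 10L, amp = 3), seed = seed)
    refl <- make_reflectance("uniform", size, list(value = 0.6))
    render_scene(height, refl, light_direction(pi / 4), ambient = 0.1,
                 seed = seed)
  },
  wing_eyespot = function(seed) {
    size <- c(96L, 96L)
    height <- make_height_field("flat", size)
    refl <- make_reflectance("eyespot", size,
                             list(radii = c(8, 16, 24),
                                  values = c(0.08, 0.85, 0.3), bg = 0.55))
    render_scene(height, refl, light_direction(0), ambient = 0.1,
                 mask = wing_mask(size), seed = seed)
  }
)

#' Build a named synthetic scene recipe
#'
#' Registry: `curled_leaf_like` (curling sheet, uniform albedo, wing
#' mask), `flat_mondrian` (zero relief, 6-patch Mondrian albedo — the
#' false-depth control), `hemisphere_uniform` (spherical cap, cap-disc
#' ROI), `bark_bumps` (random oriented bumps), `wing_eyespot` (flat wing
#' with a concentric eyespot).
#'
#' @param recipe registry name.
#' @param seed integer seed.
#' @return a `synthetic_scene`.
#' @export
make_recipe_scene <- function(recipe, seed = 1L) {
  abort_if(!recipe %in% names(.recipes),
           "unknown recipe '", recipe, "'; available: ",
           paste(names(.recipes), collapse = ", "))
  .recipes[[recipe]](as.integer(seed))
}

#' Materialize a scene recipe to disk
#'
#' @param recipe registry name (see [make_recipe_scene]).
#' @param output_dir directory to write the scene into.
#' @param seed integer seed.
#' @return the scene directory path, invisibly.
#' @export
generate_fixtures <- function(recipe, output_dir, seed = 1L) {
  scene <- make_recipe_scene(recipe, seed)
  save_scene(scene, output_dir)
  invisible(output_dir)
}

#' Evaluate the pipeline against a scene's ground truth
#'
#' Runs the reconstruction on the scene's rendered image (linear values,
#' no sRGB transfer) and reports recovery metrics over the ROI: Pearson
#' correlation between detrended recovered and detrended true height,
#' median angular error of the recovered normals (degrees), Pearson
#' correlation between recovered and true log shading, and the recovered
#' height variance and range.
#'
#' @param scene a `synthetic_scene` or a directory written by
#'   [generate_fixtures].
#' @param config a [pipeline_config].
#' @return list with `metrics` and the `pipeline_result`.
#' @export
evaluate_scene <- function(scene, config = pipeline_config()) {
  if (is.character(scene)) scene <- load_scene(scene)
  cfg <- config
  cfg$linearize_srgb <- FALSE
  res <- reconstruct_depth(scene$rendered, scene$mask, cfg)
  m <- scene$mask$inside

  true_detr <- detrend_plane(scene$true_height, scene$mask)$values
  rec <- res$height$values
  height_r <- if (stats::sd(true_detr[m]) > 0 && stats::sd(rec[m]) > 0) {
    stats::cor(rec[m], true_detr[m])
  } else NA_real_

  dotp <- res$normals[, , 1] * scene$true_normals[, , 1] +
    res$normals[, , 2] * scene$true_normals[, , 2] +
    res$normals[, , 3] * scene$true_normals[, , 3]
  ang <- acos(pmin(pmax(dotp[m], -1), 1)) * 180 / pi
  normal_median_err <- stats::median(ang)

  D <- scene$light$vector
  lam <- D[1] * scene$true_normals[, , 1] + D[2] * scene$true_normals[, , 2] +
    D[3] * scene$true_normals[, , 3]
  true_s <- pmax(lam, 0) + scene$ambient
  log_s_rec <- log(pmax(res$shading, 1e-8))
  log_s_true <- log(pmax(true_s, 1e-8))
  shading_r <- if (stats::sd(log_s_true[m]) > 0 && stats::sd(log_s_rec[m]) > 0) {
    stats::cor(log_s_rec[m], log_s_true[m])
  } else NA_real_

  list(metrics = list(height_pearson_r = height_r,
                      normal_median_angular_error_deg = normal_median_err,
                      shading_log_pearson_r = shading_r,
                      recovered_height_var = stats::var(rec[m]),
                      recovered_height_range = diff(range(rec[m]))),
       result = res)
}

# ---- command-line interface --------------------------------------------

.cli_usage <- paste(
  "pictodepth <command> [options]",
  "",
  "Commands:",
  "  reconstruct <image> --mask <mask> [--config <json>] [--out <dir>]",
  "              [--no-srgb-linearize] [--export-mesh]",
  "  synth <recipe> [--seed <n>] [--out <dir>]",
  "  evaluate <scene-dir> [--config <json>]",
  sep = "\n")

.cli_opt <- function(args, flag, default = NULL, has_value = TRUE) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (!has_value) return(TRUE)
  abort_if(i[1] == length(args), "missing value for ", flag)
  args[i[1] + 1L]
}

#' Command-line entry point
#'
#' Dispatches the `reconstruct`, `synth` and `evaluate` subcommands (see
#' `exec/pictodepth`). Returns the exit status (0 on success) instead of
#' calling `quit()`, so it is testable in-process.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(.cli_usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    if (cmd == "reconstruct") {
      image <- rest[1]
      abort_if(is.na(image) || startsWith(image, "--"),
               "reconstruct: missing <image> argument")
      mask <- .cli_opt(rest, "--mask")
      abort_if(is.null(mask), "reconstruct: --mask is required")
      cfg_path <- .cli_opt(rest, "--config")
      cfg <- if (is.null(cfg_path)) pipeline_config() else
        read_pipeline_config(cfg_path)
      if (isTRUE(.cli_opt(rest, "--no-srgb-linearize", has_value = FALSE))) {
        cfg$linearize_srgb <- FALSE
      }
      out <- .cli_opt(rest, "--out", "pictodepth_out")
      mesh <- isTRUE(.cli_opt(rest, "--export-mesh", has_value = FALSE))
      res <- run_pipeline(image, mask, cfg, out_dir = out, export_mesh = mesh)
      message("wrote ", out)
      for (s in names(res$stages)) {
        message(sprintf("stage %-10s %6.2fs residual %.3g", s,
                        res$stages[[s]]$seconds,
                        res$stages[[s]]$relative_residual))
      }
      0L
    } else if (cmd == "synth") {
      recipe <- rest[1]
      abort_if(is.na(recipe) || startsWith(recipe, "--"),
               "synth: missing <recipe> argument")
      seed <- as.integer(.cli_opt(rest, "--seed", "1"))
      out <- .cli_opt(rest, "--out", recipe)
      generate_fixtures(recipe, out, seed)
      message("wrote scene to ", out)
      0L
    } else if (cmd == "evaluate") {
      dir <- rest[1]
      abort_if(is.na(dir) || startsWith(dir, "--"),
               "evaluate: missing <scene-dir> argument")
      cfg_path <- .cli_opt(rest, "--config")
      cfg <- if (is.null(cfg_path)) pipeline_config() else
        read_pipeline_config(cfg_path)
      ev <- evaluate_scene(dir, cfg)
      for (nm in names(ev$metrics)) {
        cat(sprintf("%s: %.6g\n", nm, ev$metrics[[nm]]))
      }
      0L
    } else {
      message("unknown command: ", cmd)
      message(.cli_usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
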