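#' Light direction
#'
#' A unit illumination vector with azimuth in the image plane (x right,
#' y down) and elevation above the plane fixed at 45 degrees by default —
#' the compromise between a vertical light (every pixel lit, but no
#' directional shading) and a grazing light (maximal shading, but many
#' pixels facing away).
#'
#' @param azimuth_rad planar angle in radians, measured from +x towards +y.
#' @param elevation_rad elevation above the image plane (default `pi/4`).
#' @return a `light_direction` with fields `vector`, `azimuth_rad`,
#'   `elevation_rad`.
#' @export
light_direction <- function(azimuth_rad = 0, elevation_rad = pi / 4) {
  abort_if(!is_scalar_num(azimuth_rad) || !is_scalar_num(elevation_rad),
           "light_direction: angles must be finite scalars")
  v <- c(cos(azimuth_rad) * cos(elevation_rad),
         sin(azimuth_rad) * cos(elevation_rad),
         sin(elevation_rad))
  structure(list(vector = v, azimuth_rad = azimuth_rad,
                 elevation_rad = elevation_rad),
            class = "light_direction")
}

#' @export
print.light_direction <- function(x, ...) {
  cat(sprintf("<light_direction azimuth %.2f deg, elevation %.2f deg, D = (%.4f, %.4f, %.4f)>\n",
              x$azimuth_rad * 180 / pi, x$elevation_rad * 180 / pi,
              x$vector[1], x$vector[2], x$vector[3]))
  invisible(x)
}

#' Configuration for normal estimation
#'
#' @param data_weight weight of the Lambertian rows `<D, N> = S`
#'   (default 1).
#' @param smooth_weight weight of the normal-smoothness rows `dN = 0`
#'   (default 1).
#' @param edge_weight weight of the reflectance-edge orientation rows
#'   (default 1).
#' @param prior_weight weight of the weak fronto-parallel prior rows
#'   pulling the planar normal components toward zero (default 0.01);
#'   resolves the scale/tilt null space of constant-shading regions in
#'   favour of a viewer-facing surface.
#' @param edge_threshold_c reflectance-gradient threshold above which edge
#'   rows fire; `NULL` (default) uses the 90th percentile of the nonzero
#'   inside-mask log-reflectance gradient magnitudes (infinite if there
#'   are none, disabling the term).
#' @param solver_tol,solver_max_iter iterative least-squares controls.
#' @return a `normal_config` list.
#' @export
normal_config <- function(data_weight = 1, smooth_weight = 1,
                          edge_weight = 1, prior_weight = 0.01,
                          edge_threshold_c = NULL,
                          solver_tol = 1e-8, solver_max_iter = 10000L) {
  cfg <- list(data_weight = data_weight, smooth_weight = smooth_weight,
              edge_weight = edge_weight, prior_weight = prior_weight,
              edge_threshold_c = edge_threshold_c,
              solver_tol = solver_tol,
              solver_max_iter = as.integer(solver_max_iter))
  abort_if(any(c(cfg$data_weight, cfg$smooth_weight, cfg$edge_weight,
                 cfg$prior_weight) < 0),
           "normal_config: weights must be >= 0")
  abort_if(!is.null(cfg$edge_threshold_c) &&
             (!is_scalar_num(cfg$edge_threshold_c) || cfg$edge_threshold_c <= 0),
           "normal_config: edge_threshold_c must be > 0")
  structure(cfg, class = "normal_config")
}

#' Estimate the illumination direction from the shading map
#'
#' The planar azimuth is taken as the dominant orientation of the shading
#' gradient — the principal eigenvector of the structure tensor (the sum
#' of outer products of inside-mask forward-difference gradients).
#'
#' The orientation's 180-degree sign ambiguity is the classic
#' convex/concave flip and cannot be resolved from shading alone. The
#' convention here targets predominantly flat sheets (wings, leaves) with
#' localized relief sloping away from the light: the lit flat expanse is
#' bright and the relief dark, so the light is taken to sit *opposite*
#' the mean shading gradient (non-positive mean projection). For a fully
#' convex blob (a dome) the opposite convention would hold; see the
#' methods vignette. An exactly zero mean projection selects azimuth in
#' `[0, pi)`. Elevation is fixed at 45 degrees. Constant shading is
#' degenerate: azimuth 0 is returned with a warning.
#'
#' @param shading `H x W` shading matrix (or `decompose()$shading`).
#' @param mask a [region_mask].
#' @return a [light_direction].
#' @export
estimate_light_direction <- function(shading, mask) {
  m <- mask$inside
  g <- grad_forward(shading)
  # valid gradient samples: both pixels of each forward pair inside mask
  h <- nrow(m); w <- ncol(m)
  okx <- m & cbind(m[, -1, drop = FALSE], FALSE)
  oky <- m & rbind(m[-1, , drop = FALSE], FALSE)
  gx <- g$gx; gy <- g$gy
  gx[!okx] <- 0; gy[!oky] <- 0
  jxx <- sum(gx^2); jyy <- sum(gy^2); jxy <- sum(gx * gy)
  if (jxx + jyy < 1e-24) {
    warning("constant shading: light azimuth is degenerate, using 0",
            call. = FALSE)
    return(light_direction(0))
  }
  # principal eigenvector of [[jxx, jxy], [jxy, jyy]]
  theta <- 0.5 * atan2(2 * jxy, jxx - jyy)
  v <- c(cos(theta), sin(theta))
  # verify it is the major axis (atan2 form gives the major orientation)
  proj_major <- jxx * v[1]^2 + 2 * jxy * v[1] * v[2] + jyy * v[2]^2
  if (proj_major < (jxx + jyy) / 2) {
    v <- c(-v[2], v[1])
  }
  mp <- sum(gx * v[1] + gy * v[2])
  if (mp > 0) {
    v <- -v
  } else if (mp == 0 && atan2(v[2], v[1]) < 0) {
    v <- -v
  }
  light_direction(atan2(v[2], v[1]))
}

# pooled (channel-mean) log-reflectance gradient; returns gx, gy, magnitude
.reflectance_gradient <- function(reflectance, eps_floor = 1e-4) {
  if (is.matrix(reflectance)) {
    reflectance <- array(reflectance, c(dim(reflectance), 1L))
  }
  lr <- log(pmax(reflectance, eps_floor))
  lr_mean <- apply(lr, c(1, 2), mean)
  g <- grad_forward(lr_mean)
  list(gx = g$gx, gy = g$gy, mag = sqrt(g$gx^2 + g$gy^2))
}

#' Estimate a normal map from shading and reflectance
#'
#' Solves, in the least-squares sense over the three per-pixel normal
#' components inside the mask, the stacked sparse system
#'
#' * data rows: the Lambertian shading equation `<D, N> = S` (shading is
#'   first rescaled so its inside-mask maximum is at most 1; values
#'   brighter than a light-facing surface simply carry residual);
#' * smoothness rows: `dN = 0` between 4-neighbours inside the mask;
#' * edge rows: where the log-reflectance gradient magnitude exceeds the
#'   threshold `c`, the planar normal component is forced perpendicular to
#'   the edge via `<Rot90 grad R, (Nx, Ny)> = 0` (a 90-degree in-plane
#'   rotation of the reflectance gradient);
#' * weak fronto-parallel prior rows (see [normal_config]).
#'
#' Each solved vector is then renormalized to unit length with its z
#' component clamped to at least `1e-3` first, so normals are front-facing
#' and the downstream gradient `-(Nx/Nz, Ny/Nz)` stays finite.
#'
#' @param shading `H x W` shading matrix.
#' @param reflectance `H x W x C` reflectance array (for edge rows); pass
#'   `NULL` to disable edge rows.
#' @param light a [light_direction].
#' @param mask a [region_mask].
#' @param config a [normal_config].
#' @param method least-squares method, `"cgls"` or `"direct"`.
#' @return list with `normals` (`H x W x 3`, unit norm inside mask,
#'   `(0,0,1)` outside), `shading_scale` (rescale factor applied),
#'   `diagnostics`.
#' @export
estimate_normals <- function(shading, reflectance, light, mask,
                             config = normal_config(),
                             method = c("cgls", "direct")) {
  method <- match.arg(method)
  m <- mask$inside
  h <- nrow(m); w <- ncol(m)
  abort_if(!all(dim(shading) == c(h, w)), "estimate_normals: shape mismatch")
  smax <- max(shading[m])
  abort_if(smax <= 0, "estimate_normals: shading must be positive somewhere")
  # rescale only when values exceed 1 (brighter than any Lambertian surface
  # under a unit light); an already-valid shading map is left untouched
  smax <- max(smax, 1)
  s_scaled <- shading / smax
  abort_if(max(s_scaled[m]) > 1 + 1e-12,
           "estimate_normals: shading rescale failed")
  D <- light$vector

  n_in <- sum(m)
  idx <- matrix(NA_integer_, h, w)
  idx[m] <- seq_len(n_in)
  # unknown layout: nx block, ny block, nz block
  ix <- function(p) idx[p]
  iy <- function(p) idx[p] + n_in
  iz <- function(p) idx[p] + 2L * n_in

  ti <- list(); tj <- list(); tx <- list(); rhs <- list(); nrow_acc <- 0L
  push <- function(cols, vals, b) {
    # cols/vals: list of equal-length vectors, one entry per coefficient slot
    nr <- length(b)
    if (!nr) return(invisible(NULL))
    for (k in seq_along(cols)) {
      ti[[length(ti) + 1L]] <<- nrow_acc + seq_len(nr)
      tj[[length(tj) + 1L]] <<- cols[[k]]
      tx[[length(tx) + 1L]] <<- rep(vals[[k]], length.out = nr)
    }
    rhs[[length(rhs) + 1L]] <<- b
    nrow_acc <<- nrow_acc + nr
    invisible(NULL)
  }

  p_all <- which(m)
  wd <- sqrt(config$data_weight)
  push(list(ix(p_all), iy(p_all), iz(p_all)),
       list(wd * D[1], wd * D[2], wd * D[3]),
       b = wd * s_scaled[p_all])

  ws <- sqrt(config$smooth_weight)
  pairs_x <- {
    okx <- m[, -w, drop = FALSE] & m[, -1, drop = FALSE]
    pr <- which(okx)
    sub_r <- ((pr - 1L) %% h) + 1L
    sub_c <- ((pr - 1L) %/% h) + 1L
    p <- (sub_c - 1L) * h + sub_r
    cbind(p, p + h)
  }
  pairs_y <- {
    oky <- m[-h, , drop = FALSE] & m[-1, , drop = FALSE]
    pr <- which(oky)
    sub_r <- ((pr - 1L) %% (h - 1L)) + 1L
    sub_c <- ((pr - 1L) %/% (h - 1L)) + 1L
    p <- (sub_c - 1L) * h + sub_r
    cbind(p, p + 1L)
  }
  pairs <- rbind(pairs_x, pairs_y)
  if (nrow(pairs) && ws > 0) {
    for (comp in list(ix, iy, iz)) {
      push(list(comp(pairs[, 1]), comp(pairs[, 2])), list(-ws, ws),
           b = rep(0, nrow(pairs)))
    }
  }

  n_edge <- 0L
  cthr <- NA_real_
  if (!is.null(reflectance) && config$edge_weight > 0) {
    rg <- .reflectance_gradient(reflectance)
    cthr <- config$edge_threshold_c
    if (is.null(cthr)) {
      # 90th percentile of the nonzero gradient magnitudes: piecewise
      # constant reflectance has mostly exactly-zero gradients, and a
      # percentile over all pixels would degenerate to 0 and disable the
      # edge constraint precisely where strong edges exist
      magin <- rg$mag[m]
      magin <- magin[magin > 0]
      cthr <- if (length(magin)) {
        as.numeric(stats::quantile(magin, 0.9, names = FALSE))
      } else Inf
      if (cthr <= 0) cthr <- Inf
    }
    e_ind <- m & (rg$mag > cthr)
    p_e <- which(e_ind)
    n_edge <- length(p_e)
    if (n_edge) {
      we <- sqrt(config$edge_weight)
      # Rot90 * (gx, gy) = (-gy, gx)
      push(list(ix(p_e), iy(p_e)),
           list(-we * rg$gy[p_e], we * rg$gx[p_e]),
           b = rep(0, n_edge))
    }
  }

  wp <- sqrt(config$prior_weight)
  if (wp > 0) {
    push(list(ix(p_all)), list(wp), b = rep(0, n_in))
    push(list(iy(p_all)), list(wp), b = rep(0, n_in))
  }

  A <- triplet_matrix(unlist(ti), unlist(tj), unlist(tx),
                      nrow = nrow_acc, ncol = 3L * n_in)
  b <- unlist(rhs)
  sol <- lsq_solve(A, b, tol = config$solver_tol,
                   max_iter = config$solver_max_iter, method = method)

  nx <- sol$x[seq_len(n_in)]
  ny <- sol$x[n_in + seq_len(n_in)]
  nz <- pmax(sol$x[2L * n_in + seq_len(n_in)], 1e-3)
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  normals <- array(0, c(h, w, 3))
  normals[, , 3] <- 1
  tmp <- matrix(0, h, w)
  tmp[m] <- nx / nrm; normals[, , 1] <- tmp
  tmp <- matrix(0, h, w)
  tmp[m] <- ny / nrm; normals[, , 2] <- tmp
  tmp <- matrix(1, h, w)
  tmp[m] <- nz / nrm; normals[, , 3] <- tmp

  list(normals = normals, shading_scale = smax,
       diagnostics = list(iterations = sol$iterations,
                          relative_residual = sol$relative_residual,
                          residual_norm = sol$residual_norm,
                          n_rows = nrow_acc, n_unknowns = 3L * n_in,
                          n_edge_rows = n_edge,
                          edge_threshold = cthr))
}
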