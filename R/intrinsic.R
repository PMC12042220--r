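#' Configuration for intrinsic image decomposition
#'
#' Weights and thresholds of the regularized log-space decomposition
#' objective: a Retinex term (small log-intensity gradients are shading,
#' large ones are reflectance edges), a texture term (patches with
#' correlated texture share reflectance) and a scale term pinning the log
#' shading of the brightest pixels to zero, which removes the global
#' multiplicative ambiguity of `I = R x S`.
#'
#' @param lambda_rx weight of the Retinex term (default 1).
#' @param lambda_tx weight of the texture term (default 1).
#' @param lambda_sc weight of the scale term (default 1000; it touches only
#'   the few brightest pixels, so it must be enforced much more strongly).
#' @param retinex_threshold_t gradient-magnitude threshold in log-intensity
#'   units separating shading gradients from reflectance edges
#'   (default 0.1).
#' @param retinex_smooth_weight the omega value applied below threshold
#'   (default 100).
#' @param edge_weight_zero the omega value above threshold (default 0).
#' @param brightness_quantile fraction of the maximum brightness above
#'   which a pixel counts as "brightest" for the scale term (default 0.95).
#' @param texture_patch_px odd patch side for texture matching (default 5).
#' @param texture_knn neighbours linked per patch (default 4).
#' @param texture_corr_min normalized-correlation threshold for linking
#'   patches (default 0.9).
#' @param texture_stride candidate-grid stride in pixels (default 2).
#' @param texture_max_candidates cap on candidate patches; excess candidates
#'   are subsampled with `rng_seed` (default 1500).
#' @param texture_min_sd minimum patch standard deviation (in log units)
#'   for a patch to count as textured (default 1e-8).
#' @param texture_min_edge_frac minimum fraction of patch pixels whose
#'   pooled log gradient exceeds `retinex_threshold_t` for the patch to
#'   count as textured (default 0.3). Texture means dense repeated
#'   structure: a smooth shading ramp (no edges) or an isolated contour
#'   between two flat regions (one thin line of edges) is not texture,
#'   and linking such patches would force shading to absorb albedo
#'   differences.
#' @param texture_max_sd_ratio maximum contrast ratio (of patch standard
#'   deviations) between linked patches (default 1.25); normalized
#'   correlation alone cannot tell a strong step edge from a weak one.
#' @param solver_tol,solver_max_iter iterative least-squares controls.
#' @param rng_seed seed for any candidate subsampling.
#' @return a `decomposition_config` list.
#' @export
decomposition_config <- function(lambda_rx = 1, lambda_tx = 1,
                                 lambda_sc = 1000,
                                 retinex_threshold_t = 0.1,
                                 retinex_smooth_weight = 100,
                                 edge_weight_zero = 0,
                                 brightness_quantile = 0.95,
                                 texture_patch_px = 5L,
                                 texture_knn = 4L,
                                 texture_corr_min = 0.9,
                                 texture_stride = 2L,
                                 texture_max_candidates = 1500L,
                                 texture_min_sd = 1e-8,
                                 texture_min_edge_frac = 0.3,
                                 texture_max_sd_ratio = 1.25,
                                 solver_tol = 1e-8,
                                 solver_max_iter = 10000L,
                                 rng_seed = 1L) {
  cfg <- list(lambda_rx = lambda_rx, lambda_tx = lambda_tx,
              lambda_sc = lambda_sc,
              retinex_threshold_t = retinex_threshold_t,
              retinex_smooth_weight = retinex_smooth_weight,
              edge_weight_zero = edge_weight_zero,
              brightness_quantile = brightness_quantile,
              texture_patch_px = as.integer(texture_patch_px),
              texture_knn = as.integer(texture_knn),
              texture_corr_min = texture_corr_min,
              texture_stride = as.integer(texture_stride),
              texture_max_candidates = as.integer(texture_max_candidates),
              texture_min_sd = texture_min_sd,
              texture_min_edge_frac = texture_min_edge_frac,
              texture_max_sd_ratio = texture_max_sd_ratio,
              solver_tol = solver_tol,
              solver_max_iter = as.integer(solver_max_iter),
              rng_seed = as.integer(rng_seed))
  abort_if(any(c(cfg$lambda_rx, cfg$lambda_tx, cfg$lambda_sc) < 0),
           "decomposition_config: weights must be >= 0")
  abort_if(cfg$brightness_quantile <= 0 || cfg$brightness_quantile >= 1,
           "decomposition_config: brightness_quantile must lie in (0, 1)")
  abort_if(cfg$texture_patch_px < 3L || cfg$texture_patch_px %% 2L == 0L,
           "decomposition_config: texture_patch_px must be odd and >= 3")
  structure(cfg, class = "decomposition_config")
}

#' Retinex edge/shading weight raster
#'
#' Classifies each pixel's log-intensity gradient: weight 0 where the
#' pooled gradient magnitude exceeds the threshold `t` (a reflectance
#' edge, excluded from shading smoothing) and `smooth_weight` (default
#' 100) otherwise. Gradients are forward differences; for colour images
#' the magnitude is the maximum over channels.
#'
#' @param log_image a [to_log] result (or plain numeric array of logs).
#' @param t positive gradient threshold in log units.
#' @param smooth_weight weight below threshold (default 100).
#' @return `H x W` numeric matrix containing only `{0, smooth_weight}`.
#' @export
retinex_weight <- function(log_image, t, smooth_weight = 100) {
  abort_if(!is_scalar_num(t) || t <= 0, "retinex_weight: t must be > 0")
  lp <- if (inherits(log_image, "log_image")) log_image$log_pixels else log_image
  if (is.matrix(lp)) lp <- array(lp, c(dim(lp), 1L))
  d <- dim(lp)
  mag <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) {
    g <- grad_forward(lp[, , c])
    mag <- pmax(mag, sqrt(g$gx^2 + g$gy^2))
  }
  ifelse(mag > t, 0, smooth_weight)
}

#' Brightest-pixel indicator for the scale constraint
#'
#' Flags pixels at least as bright as `quantile` (default 95%) of the
#' brightest pixel in the image; brightness is the per-pixel maximum over
#' channels. These pixels anchor the scale of the shading map (their log
#' shading is pulled to zero, i.e. shading 1).
#'
#' @param image a [radiance_image] (or numeric array in `[0, 1]`).
#' @param quantile fraction of the maximum brightness (default 0.95).
#' @return `H x W` binary (0/1) matrix.
#' @export
scale_indicator <- function(image, quantile = 0.95) {
  px <- if (inherits(image, "radiance_image")) image$pixels else image
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  bright <- px[, , 1]
  if (dim(px)[3] > 1L) for (c in 2:dim(px)[3]) bright <- pmax(bright, px[, , c])
  (bright >= quantile * max(bright)) * 1
}

# patch extraction helper: returns matrix (n_candidates x patch_px^2) of
# mean-subtracted channel-averaged log intensities, plus candidate indices
.texture_candidates <- function(lp_mean, mask, cfg) {
  h <- nrow(lp_mean); w <- ncol(lp_mean)
  half <- (cfg$texture_patch_px - 1L) %/% 2L
  rows <- seq(half + 1L, h - half, by = cfg$texture_stride)
  cols <- seq(half + 1L, w - half, by = cfg$texture_stride)
  if (!length(rows) || !length(cols)) {
    return(list(centers = integer(0), patches = NULL))
  }
  grid <- expand.grid(r = rows, c = cols)
  # center must be inside the mask and the whole patch inside too
  ok <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    r <- grid$r[k]; c <- grid$c[k]
    ok[k] <- all(mask[(r - half):(r + half), (c - half):(c + half)])
  }
  grid <- grid[ok, , drop = FALSE]
  n <- nrow(grid)
  if (n > cfg$texture_max_candidates) {
    keep <- with_seed(cfg$rng_seed,
                      sort(sample.int(n, cfg$texture_max_candidates)))
    grid <- grid[keep, , drop = FALSE]
    n <- nrow(grid)
  }
  if (n == 0L) return(list(centers = integer(0), patches = NULL))
  pside <- cfg$texture_patch_px
  patches <- matrix(0, n, pside * pside)
  for (k in seq_len(n)) {
    p <- lp_mean[(grid$r[k] - half):(grid$r[k] + half),
                 (grid$c[k] - half):(grid$c[k] + half)]
    patches[k, ] <- as.numeric(p) - mean(p)
  }
  centers <- (grid$c - 1L) * h + grid$r   # column-major linear index
  list(centers = centers, patches = patches,
       rr = grid$r, cc = grid$c)
}

#' Texture pair links between similarly textured patches
#'
#' Finds pairs of locations whose mean-subtracted local log-intensity
#' patches have normalized cross-correlation at least
#' `texture_corr_min`; the decomposition forces equal reflectance across
#' each link. Candidates sit on a stride grid (default every 2 px) fully
#' inside the mask; near-flat patches (below `texture_min_sd`) carry no
#' texture and are skipped, as are pairs closer than one patch side
#' (overlapping patches correlate trivially). Each candidate links to at
#' most `texture_knn` best-correlated partners. Deterministic given
#' `rng_seed`.
#'
#' @param log_image a [to_log] result.
#' @param mask a [region_mask].
#' @param config a [decomposition_config].
#' @return a `texture_pair_set`: list with integer vectors `i`, `j`
#'   (column-major pixel indices, i < j) and numeric `weight`.
#' @export
texture_pairs <- function(log_image, mask, config = decomposition_config()) {
  lp <- log_image$log_pixels
  if (is.matrix(lp)) lp <- array(lp, c(dim(lp), 1L))
  lp_mean <- apply(lp, c(1, 2), mean)
  m <- mask$inside
  cand <- .texture_candidates(lp_mean, m, config)
  empty <- structure(list(i = integer(0), j = integer(0), weight = numeric(0)),
                     class = "texture_pair_set")
  if (is.null(cand$patches)) return(empty)
  # a patch counts as textured only if a substantial fraction of its
  # pixels carry above-threshold gradients (dense repeated structure).
  # Smooth shading ramps have nonzero variance but no edges; an isolated
  # straight contour (a patch boundary) has edges on only a thin line —
  # both would otherwise create links that force shading to absorb albedo
  # differences
  gm <- matrix(0, nrow(lp_mean), ncol(lp_mean))
  for (c in seq_len(dim(lp)[3])) {
    g <- grad_forward(lp[, , c])
    gm <- pmax(gm, sqrt(g$gx^2 + g$gy^2))
  }
  half <- (config$texture_patch_px - 1L) %/% 2L
  edge_frac <- vapply(seq_along(cand$centers), function(k) {
    mean(gm[(cand$rr[k] - half):(cand$rr[k] + half),
            (cand$cc[k] - half):(cand$cc[k] + half)] >
           config$retinex_threshold_t)
  }, numeric(1))
  sds <- apply(cand$patches, 1, stats::sd)
  keep <- edge_frac >= config$texture_min_edge_frac &
    sds > config$texture_min_sd
  if (sum(keep) < 2L) return(empty)
  P <- cand$patches[keep, , drop = FALSE]
  centers <- cand$centers[keep]
  rr <- cand$rr[keep]; cc <- cand$cc[keep]
  sds <- sds[keep]
  Pn <- P / sqrt(rowSums(P^2))
  C <- Pn %*% t(Pn)
  # normalized correlation discards contrast; two step edges of different
  # strength would match. Restrict links to patches of similar contrast.
  sd_ratio <- outer(sds, sds, function(a, b) pmax(a, b) / pmin(a, b))
  C[sd_ratio > config$texture_max_sd_ratio] <- -Inf
  n <- nrow(C)
  mindist <- config$texture_patch_px
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(n)) {
    corr <- C[k, ]
    corr[k] <- -Inf
    near <- abs(rr - rr[k]) < mindist & abs(cc - cc[k]) < mindist
    corr[near] <- -Inf
    elig <- which(corr >= config$texture_corr_min)
    if (!length(elig)) next
    top <- elig[order(corr[elig], decreasing = TRUE)]
    top <- top[seq_len(min(length(top), config$texture_knn))]
    ii <- c(ii, rep(k, length(top)))
    jj <- c(jj, top)
  }
  if (!length(ii)) return(empty)
  a <- pmin(centers[ii], centers[jj])
  b <- pmax(centers[ii], centers[jj])
  dedup <- !duplicated(cbind(a, b))
  structure(list(i = a[dedup], j = b[dedup],
                 weight = rep(1, sum(dedup))),
            class = "texture_pair_set")
}

#' Intrinsic image decomposition into reflectance and shading
#'
#' Splits an image into a monochromatic shading map `S` and a per-channel
#' reflectance map `R` with `I = R x S`, by solving a sparse linear
#' least-squares problem in `log S` assembled from three row families:
#'
#' * Retinex rows: for every inside-mask 4-neighbour pair and channel, the
#'   residual `omega * d(log I) + (1 - omega) * d(log S)`, where `omega` is
#'   the [retinex_weight] of the upstream pixel — below-threshold gradients
#'   are pushed into shading, reflectance edges into `R`;
#' * texture rows: equal log reflectance across every [texture_pairs] link;
#' * scale rows: `log S = 0` at the brightest pixels (the
#'   [scale_indicator] rule applied within the mask), weighted
#'   `sqrt(lambda_sc)`.
#'
#' Each term's rows are scaled by the square root of its lambda weight so
#' the stacked system minimizes the weighted sum of squared norms.
#'
#' @param image a [radiance_image].
#' @param mask a [region_mask].
#' @param config a [decomposition_config].
#' @param eps_floor log clamp forwarded to [to_log].
#' @param method least-squares method, `"cgls"` or `"direct"`.
#' @return list with `reflectance` (`H x W x C`, positive inside mask),
#'   `shading` (`H x W`, positive inside mask, 1 outside), `log_shading`,
#'   `diagnostics` (solver iterations, relative residual, row counts,
#'   texture pair count).
#' @export
decompose <- function(image, mask, config = decomposition_config(),
                      eps_floor = 1e-4, method = c("cgls", "direct")) {
  method <- match.arg(method)
  m <- mask$inside
  px <- image$pixels
  abort_if(!all(dim(m) == dim(px)[1:2]), "decompose: mask/image shape mismatch")
  abort_if(max(px[rep_len(m, length(px))]) == 0,
           "decompose: masked region is all black")
  h <- nrow(m); w <- ncol(m); nc <- dim(px)[3]
  lg <- to_log(image, eps_floor)
  lp <- lg$log_pixels
  if (is.matrix(lp)) lp <- array(lp, c(dim(lp), 1L))

  idx <- matrix(NA_integer_, h, w)
  idx[m] <- seq_len(sum(m))
  n_unknown <- sum(m)

  omega <- retinex_weight(lg, config$retinex_threshold_t,
                          config$retinex_smooth_weight)

  ti <- list(); tj <- list(); tx <- list(); rhs <- list()
  nrow_acc <- 0L
  add_rows <- function(p_idx, q_idx, coef_p, coef_q, b) {
    nr <- length(p_idx)
    if (!nr) return(invisible(NULL))
    ti[[length(ti) + 1L]] <<- c(nrow_acc + seq_len(nr), nrow_acc + seq_len(nr))
    tj[[length(tj) + 1L]] <<- c(p_idx, q_idx)
    tx[[length(tx) + 1L]] <<- c(coef_p, coef_q)
    rhs[[length(rhs) + 1L]] <<- b
    nrow_acc <<- nrow_acc + nr
    invisible(NULL)
  }
  add_single <- function(p_idx, coef, b) {
    nr <- length(p_idx)
    if (!nr) return(invisible(NULL))
    ti[[length(ti) + 1L]] <<- nrow_acc + seq_len(nr)
    tj[[length(tj) + 1L]] <<- p_idx
    tx[[length(tx) + 1L]] <<- rep(coef, length.out = nr)
    rhs[[length(rhs) + 1L]] <<- b
    nrow_acc <<- nrow_acc + nr
    invisible(NULL)
  }

  srx <- sqrt(config$lambda_rx)
  # Retinex rows, horizontal then vertical neighbour pairs
  for (dir in c("x", "y")) {
    if (dir == "x") {
      pr <- which(m[, -w, drop = FALSE] & m[, -1, drop = FALSE])
      # which() indexes the (h x (w-1)) submatrix; convert to full grid
      sub_r <- ((pr - 1L) %% h) + 1L
      sub_c <- ((pr - 1L) %/% h) + 1L
      p_full <- (sub_c - 1L) * h + sub_r
      q_full <- p_full + h
    } else {
      pr <- which(m[-h, , drop = FALSE] & m[-1, , drop = FALSE])
      sub_r <- ((pr - 1L) %% (h - 1L)) + 1L
      sub_c <- ((pr - 1L) %/% (h - 1L)) + 1L
      p_full <- (sub_c - 1L) * h + sub_r
      q_full <- p_full + 1L
    }
    om <- omega[p_full]
    for (c in seq_len(nc)) {
      dlogI <- lp[, , c][q_full] - lp[, , c][p_full]
      add_rows(idx[p_full], idx[q_full],
               coef_p = -srx * (1 - om), coef_q = srx * (1 - om),
               b = -srx * om * dlogI)
    }
  }

  # texture rows
  tp <- if (config$lambda_tx > 0) texture_pairs(lg, mask, config) else
    structure(list(i = integer(0), j = integer(0), weight = numeric(0)),
              class = "texture_pair_set")
  if (length(tp$i)) {
    stx <- sqrt(config$lambda_tx) * tp$weight
    for (c in seq_len(nc)) {
      dlogI <- lp[, , c][tp$i] - lp[, , c][tp$j]
      add_rows(idx[tp$i], idx[tp$j], coef_p = stx, coef_q = -stx,
               b = stx * dlogI)
    }
  }

  # scale rows: brightest pixels inside the mask
  bright <- px[, , 1]
  if (nc > 1L) for (c in 2:nc) bright <- pmax(bright, px[, , c])
  bmax <- max(bright[m])
  b_ind <- m & (bright >= config$brightness_quantile * bmax)
  ssc <- sqrt(config$lambda_sc)
  add_single(idx[b_ind], ssc, rep(0, sum(b_ind)))

  A <- triplet_matrix(unlist(ti), unlist(tj), unlist(tx),
                      nrow = nrow_acc, ncol = n_unknown)
  b <- unlist(rhs)
  sol <- lsq_solve(A, b, tol = config$solver_tol,
                   max_iter = config$solver_max_iter, method = method)

  log_s <- matrix(0, h, w)
  log_s[m] <- sol$x
  shading <- matrix(1, h, w)
  shading[m] <- exp(sol$x)
  refl <- array(1, c(h, w, nc))
  for (c in seq_len(nc)) {
    rc <- matrix(1, h, w)
    rc[m] <- exp(lp[, , c][m] - log_s[m])
    refl[, , c] <- rc
  }
  list(reflectance = refl, shading = shading, log_shading = log_s,
       diagnostics = list(iterations = sol$iterations,
                          relative_residual = sol$relative_residual,
                          residual_norm = sol$residual_norm,
                          n_rows = nrow_acc, n_unknowns = n_unknown,
                          n_texture_pairs = length(tp$i),
                          n_scale_pixels = sum(b_ind)))
}
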