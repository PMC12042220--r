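# Independent oracles used across the suite. These deliberately use naive
# constructions (per-pixel loops, dense linear algebra, breadth-first path
# integration) so they share no code path with the package's sparse
# vectorized implementations.

# Exact integral of a curl-free forward-difference gradient field by
# breadth-first traversal from the anchor pixel.
oracle_path_integrate <- function(gx, gy, mask, anchor) {
  h <- nrow(mask); w <- ncol(mask)
  H <- matrix(NA_real_, h, w)
  H[anchor] <- 0
  queue <- anchor
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- ((p - 1) %% h) + 1; c <- ((p - 1) %/% h) + 1
    # neighbours with the forward-difference convention
    # right: H[r, c+1] = H[r, c] + gx[r, c]
    if (c < w && mask[r, c + 1] && is.na(H[r, c + 1])) {
      H[r, c + 1] <- H[r, c] + gx[r, c]
      queue <- c(queue, (c) * h + r)
    }
    if (c > 1 && mask[r, c - 1] && is.na(H[r, c - 1])) {
      H[r, c - 1] <- H[r, c] - gx[r, c - 1]
      queue <- c(queue, (c - 2) * h + r)
    }
    if (r < h && mask[r + 1, c] && is.na(H[r + 1, c])) {
      H[r + 1, c] <- H[r, c] + gy[r, c]
      queue <- c(queue, (c - 1) * h + r + 1)
    }
    if (r > 1 && mask[r - 1, c] && is.na(H[r - 1, c])) {
      H[r - 1, c] <- H[r, c] - gy[r - 1, c]
      queue <- c(queue, (c - 1) * h + r - 1)
    }
  }
  H
}

# Dense least-squares assembly of the decomposition objective by explicit
# per-pixel loops; solved with base qr.solve on the normal equations.
oracle_dense_decompose <- function(image, mask, cfg = decomposition_config()) {
  px <- image$pixels
  m <- mask$inside
  h <- nrow(m); w <- ncol(m); nc <- dim(px)[3]
  lp <- log(pmax(px, 1e-4))
  idx <- matrix(NA_integer_, h, w)
  idx[m] <- seq_len(sum(m))
  n <- sum(m)
  rows <- list(); bs <- numeric(0)
  omega <- retinex_weight(to_log(image), cfg$retinex_threshold_t,
                          cfg$retinex_smooth_weight)
  add <- function(coefs, b) {
    rows[[length(rows) + 1L]] <<- coefs
    bs <<- c(bs, b)
  }
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    om <- omega[r, c]
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > h || c2 > w || !m[r2, c2]) next
      for (ch in seq_len(nc)) {
        dlogI <- lp[r2, c2, ch] - lp[r, c, ch]
        coefs <- numeric(n)
        coefs[idx[r2, c2]] <- (1 - om)
        coefs[idx[r, c]] <- -(1 - om)
        add(sqrt(cfg$lambda_rx) * coefs, -sqrt(cfg$lambda_rx) * om * dlogI)
      }
    }
  }
  bright <- apply(px, c(1, 2), max)
  bmax <- max(bright[m])
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    if (bright[r, c] >= cfg$brightness_quantile * bmax) {
      coefs <- numeric(n)
      coefs[idx[r, c]] <- sqrt(cfg$lambda_sc)
      add(coefs, 0)
    }
  }
  A <- do.call(rbind, rows)
  x <- qr.solve(crossprod(A), crossprod(A, bs))
  log_s <- matrix(0, h, w)
  log_s[m] <- x
  log_s
}

# Dense assembly of the normal-estimation objective (no edge rows).
oracle_dense_normals <- function(shading, light, mask,
                                 cfg = normal_config()) {
  m <- mask$inside
  h <- nrow(m); w <- ncol(m)
  s <- shading / max(max(shading[m]), 1)
  idx <- matrix(NA_integer_, h, w)
  idx[m] <- seq_len(sum(m))
  n <- sum(m)
  D <- light$vector
  rows <- list(); bs <- numeric(0)
  add <- function(coefs, b) {
    rows[[length(rows) + 1L]] <<- coefs
    bs <<- c(bs, b)
  }
  comp <- function(p, k) (k - 1L) * n + p
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    p <- idx[r, c]
    coefs <- numeric(3 * n)
    coefs[comp(p, 1)] <- D[1]; coefs[comp(p, 2)] <- D[2]
    coefs[comp(p, 3)] <- D[3]
    add(sqrt(cfg$data_weight) * coefs, sqrt(cfg$data_weight) * s[r, c])
    for (k in 1:2) {
      coefs <- numeric(3 * n)
      coefs[comp(p, k)] <- sqrt(cfg$prior_weight)
      add(coefs, 0)
    }
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > h || c2 > w || !m[r2, c2]) next
      q <- idx[r2, c2]
      for (k in 1:3) {
        coefs <- numeric(3 * n)
        coefs[comp(q, k)] <- sqrt(cfg$smooth_weight)
        coefs[comp(p, k)] <- -sqrt(cfg$smooth_weight)
        add(coefs, 0)
      }
    }
  }
  A <- do.call(rbind, rows)
  x <- qr.solve(crossprod(A), crossprod(A, bs))
  list(nx = x[seq_len(n)], ny = x[n + seq_len(n)], nz = x[2 * n + seq_len(n)],
       idx = idx)
}

# All-pairs brute-force patch correlation on a small image; mirrors the
# texture_pairs contract (edge-density gate, contrast gate, knn, min
# distance) with naive loops.
oracle_texture_pairs <- function(log_image, mask, cfg) {
  lp <- log_image$log_pixels
  if (is.matrix(lp)) lp <- array(lp, c(dim(lp), 1L))
  lpm <- apply(lp, c(1, 2), mean)
  gm <- matrix(0, nrow(lpm), ncol(lpm))
  for (ch in seq_len(dim(lp)[3])) {
    g <- pictodepth:::grad_forward(lp[, , ch])
    gm <- pmax(gm, sqrt(g$gx^2 + g$gy^2))
  }
  h <- nrow(lpm); w <- ncol(lpm)
  half <- (cfg$texture_patch_px - 1) %/% 2
  cand <- list()
  # enumerate column-major (r fastest) to match the implementation's
  # candidate order: k-nearest selection breaks correlation ties by
  # candidate position, so the enumeration order is part of the contract
  for (c in seq(half + 1, w - half, by = cfg$texture_stride)) {
    for (r in seq(half + 1, h - half, by = cfg$texture_stride)) {
      if (!all(mask$inside[(r - half):(r + half), (c - half):(c + half)])) next
      patch <- lpm[(r - half):(r + half), (c - half):(c + half)]
      v <- as.numeric(patch) - mean(patch)
      ef <- mean(gm[(r - half):(r + half), (c - half):(c + half)] >
                   cfg$retinex_threshold_t)
      if (ef < cfg$texture_min_edge_frac) next
      if (stats::sd(v) <= cfg$texture_min_sd) next
      cand[[length(cand) + 1L]] <- list(r = r, c = c, v = v,
                                        sdv = stats::sd(v),
                                        lin = (c - 1) * h + r)
    }
  }
  edges <- list()
  for (a in seq_along(cand)) {
    cors <- sapply(seq_along(cand), function(b) {
      if (b == a) return(-Inf)
      if (abs(cand[[a]]$r - cand[[b]]$r) < cfg$texture_patch_px &&
          abs(cand[[a]]$c - cand[[b]]$c) < cfg$texture_patch_px) return(-Inf)
      rat <- max(cand[[a]]$sdv, cand[[b]]$sdv) /
        min(cand[[a]]$sdv, cand[[b]]$sdv)
      if (rat > cfg$texture_max_sd_ratio) return(-Inf)
      sum(cand[[a]]$v * cand[[b]]$v) /
        sqrt(sum(cand[[a]]$v^2) * sum(cand[[b]]$v^2))
    })
    elig <- which(cors >= cfg$texture_corr_min)
    if (!length(elig)) next
    top <- elig[order(cors[elig], decreasing = TRUE)]
    top <- top[seq_len(min(length(top), cfg$texture_knn))]
    for (b in top) {
      edges[[length(edges) + 1L]] <- sort(c(cand[[a]]$lin, cand[[b]]$lin))
    }
  }
  if (!length(edges)) return(matrix(integer(0), 0, 2))
  em <- unique(do.call(rbind, edges))
  em[order(em[, 1], em[, 2]), , drop = FALSE]
}

median_angular_error_deg <- function(normals, true_normals, inside) {
  dotp <- normals[, , 1] * true_normals[, , 1] +
    normals[, , 2] * true_normals[, , 2] +
    normals[, , 3] * true_normals[, , 3]
  stats::median(acos(pmin(pmax(dotp[inside], -1), 1)) * 180 / pi)
}

# clockwise raster rotation used by the equivariance tests
rot_cw <- function(M) t(M[nrow(M):1, , drop = FALSE])
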