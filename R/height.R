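#' Height gradient from a normal map
#'
#' For a surface `z = H(x, y)` with unit normal `N`, the height gradient
#' is `grad H = -(Nx/Nz, Ny/Nz)`. Finite inside the mask because the
#' normal solver clamps `Nz` away from zero; zero outside the mask.
#'
#' @param normals `H x W x 3` unit-normal array (inside mask).
#' @param mask a [region_mask].
#' @return list (class `gradient_field`) with matrices `gx`, `gy`.
#' @export
normals_to_gradient <- function(normals, mask) {
  m <- mask$inside
  nz <- normals[, , 3]
  abort_if(any(nz[m] < 1e-4),
           "normals_to_gradient: Nz below clamp floor inside mask (upstream contract violated)")
  gx <- matrix(0, nrow(m), ncol(m))
  gy <- matrix(0, nrow(m), ncol(m))
  gx[m] <- -normals[, , 1][m] / nz[m]
  gy[m] <- -normals[, , 2][m] / nz[m]
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

#' Integrate a gradient field into a height map
#'
#' Solves, in least squares, the forward-difference equations
#' `H(x+1, y) - H(x, y) = gx` and `H(x, y+1) - H(x, y) = gy` over all
#' inside-mask 4-neighbour pairs, with one extra row pinning the anchor —
#' the first mask-border pixel in row-major scan order — to height 0.
#' For a curl-free field on a simply connected mask the solution is exact
#' (the discrete integral); for inconsistent fields (the typical case when
#' flat high-contrast patterns masquerade as relief) it is the
#' least-squares compromise surface, with the residual reported.
#'
#' @param grad a `gradient_field` from [normals_to_gradient] (or a list
#'   with matrices `gx`, `gy`; the forward-difference convention is
#'   `gx[r, c] = H[r, c+1] - H[r, c]`).
#' @param mask a [region_mask] (4-connected).
#' @param method least-squares method, `"cgls"` or `"direct"`.
#' @param solver_tol,solver_max_iter solver controls.
#' @return a `height_map`: list with `values` (`H x W`, 0 outside mask),
#'   `anchor_index` (column-major linear index), `detrended` (`FALSE`),
#'   `diagnostics`.
#' @export
integrate_height <- function(grad, mask, method = c("cgls", "direct"),
                             solver_tol = 1e-10, solver_max_iter = 20000L) {
  method <- match.arg(method)
  m <- mask$inside
  h <- nrow(m); w <- ncol(m)
  n_in <- sum(m)
  idx <- matrix(NA_integer_, h, w)
  idx[m] <- seq_len(n_in)

  border <- mask_border(m)
  border_lin <- which(border)
  abort_if(!length(border_lin), "integrate_height: mask has no border pixel")
  # first border pixel in row-major scan order
  rm_rank <- (((border_lin - 1L) %% h)) * w + ((border_lin - 1L) %/% h)
  anchor <- border_lin[which.min(rm_rank)]

  okx <- m[, -w, drop = FALSE] & m[, -1, drop = FALSE]
  pr <- which(okx)
  px <- ((pr - 1L) %/% h + 1L - 1L) * h + ((pr - 1L) %% h) + 1L
  qx <- px + h
  oky <- m[-h, , drop = FALSE] & m[-1, , drop = FALSE]
  pr <- which(oky)
  py <- ((pr - 1L) %/% (h - 1L)) * h + ((pr - 1L) %% (h - 1L)) + 1L
  qy <- py + 1L

  n_pairs <- length(px) + length(py)
  rows <- seq_len(n_pairs)
  i <- c(rows, rows, n_pairs + 1L)
  j <- c(idx[c(px, py)], idx[c(qx, qy)], idx[anchor])
  x <- c(rep(-1, n_pairs), rep(1, n_pairs), 1)
  b <- c(grad$gx[px], grad$gy[py], 0)
  A <- triplet_matrix(i, j, x, nrow = n_pairs + 1L, ncol = n_in)
  sol <- lsq_solve(A, b, tol = solver_tol, max_iter = solver_max_iter,
                   method = method)

  values <- matrix(0, h, w)
  values[m] <- sol$x - sol$x[idx[anchor]]
  structure(list(values = values, anchor_index = anchor, detrended = FALSE,
                 diagnostics = list(iterations = sol$iterations,
                                    relative_residual = sol$relative_residual,
                                    residual_norm = sol$residual_norm,
                                    n_rows = n_pairs + 1L,
                                    n_unknowns = n_in)),
            class = "height_map")
}

#' Subtract the best-fit plane from a height map
#'
#' Fits `a*x + b*y + c` by unweighted ordinary least squares to the
#' inside-mask heights and subtracts it, so that on average the surface is
#' flat and only nonlinear relief remains. This compensates for the
#' arbitrary 45-degree incident-light assumption, which can tilt the
#' reconstruction. Idempotent.
#'
#' @param height a `height_map` (or plain matrix).
#' @param mask a [region_mask].
#' @return a `height_map` with `detrended = TRUE` and plane coefficients
#'   in `diagnostics$plane`.
#' @export
detrend_plane <- function(height, mask) {
  m <- mask$inside
  vals <- if (inherits(height, "height_map")) height$values else height
  abort_if(!all(dim(vals) == dim(m)), "detrend_plane: shape mismatch")
  lin <- which(m)
  abort_if(length(lin) < 3L, "detrend_plane: need at least 3 inside pixels")
  x <- (lin - 1L) %/% nrow(m)   # 0-based column
  y <- (lin - 1L) %% nrow(m)    # 0-based row
  X <- cbind(1, x, y)
  qrX <- qr(X)
  abort_if(qrX$rank < 3L,
           "detrend_plane: inside-mask pixels are collinear; plane fit is degenerate")
  beta <- qr.coef(qrX, vals[lin])
  out <- matrix(0, nrow(m), ncol(m))
  out[lin] <- vals[lin] - X %*% beta
  diag_prev <- if (inherits(height, "height_map")) height$diagnostics else list()
  structure(list(values = out,
                 anchor_index = if (inherits(height, "height_map")) height$anchor_index else NA_integer_,
                 detrended = TRUE,
                 diagnostics = c(diag_prev,
                                 list(plane = c(intercept = beta[1],
                                                slope_x = beta[2],
                                                slope_y = beta[3])))),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<height_map %d x %d, range [%.4g, %.4g], detrended: %s>\n",
              nrow(v), ncol(v), min(v), max(v), x$detrended))
  invisible(x)
}
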