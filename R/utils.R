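#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix crossprod t Diagonal
#' @importFrom stats quantile rnorm runif sd median lm coef
#' @importFrom utils modifyList
NULL

abort_if <- function(cond, ..., class = "pictodepth_error") {
  if (cond) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
  }
  invisible(NULL)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Forward-difference gradient of a 2-D field
#'
#' Computes forward differences `gx[i,j] = f[i, j+1] - f[i, j]` (x = column,
#' increasing rightwards) and `gy[i,j] = f[i+1, j] - f[i, j]` (y = row,
#' increasing downwards), with replicate (Neumann) boundary handling: the
#' last column of `gx` and last row of `gy` are zero.
#'
#' @param f numeric matrix.
#' @return list with matrices `gx`, `gy` of the same shape as `f`.
#' @keywords internal
grad_forward <- function(f) {
  h <- nrow(f); w <- ncol(f)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  if (w > 1L) gx[, -w] <- f[, -1L, drop = FALSE] - f[, -w, drop = FALSE]
  if (h > 1L) gy[-h, ] <- f[-1L, , drop = FALSE] - f[-h, , drop = FALSE]
  list(gx = gx, gy = gy)
}

# 4-connected component labelling of a logical matrix, by vectorized
# label propagation (each pass pulls the minimum label from the 4
# neighbourhood; converges in O(diameter) passes).
label_components4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  labx <- matrix(big, h, w)
  repeat {
    labx[mask] <- lab[mask]
    nb <- labx
    if (h > 1L) {
      nb[-1L, ] <- pmin(nb[-1L, ], labx[-h, ])
      nb[-h, ] <- pmin(nb[-h, ], labx[-1L, ])
    }
    if (w > 1L) {
      nb[, -1L] <- pmin(nb[, -1L], labx[, -w])
      nb[, -w] <- pmin(nb[, -w], labx[, -1L])
    }
    new <- ifelse(mask, pmin(lab, ifelse(nb == big, lab, nb)), 0L)
    if (identical(new, lab)) break
    lab <- new
  }
  # compress labels to 1..k
  u <- sort(unique(lab[mask]))
  out <- matrix(0L, h, w)
  out[mask] <- match(lab[mask], u)
  out
}

# boundary of the true set: true pixels with at least one 4-neighbour that
# is false or outside the image
mask_border <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !core
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
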