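make_img <- function(px) radiance_image(px)
full_mask <- function(h, w) region_mask(matrix(TRUE, h, w))

test_that("retinex_weight implements the hard 0/100 rule", {
  # a step of 0.5 in log units with t = 0.1 -> edge (0); flat -> 100
  px <- array(0.3, c(8, 8, 1))
  px[, 5:8, 1] <- 0.3 * exp(0.5)
  wgt <- retinex_weight(to_log(make_img(px)), t = 0.1)
  expect_true(all(wgt %in% c(0, 100)))
  expect_equal(wgt[3, 4], 0)     # pixel whose forward difference crosses the step
  expect_equal(wgt[3, 2], 100)   # interior flat pixel
  # constant image: weight 100 everywhere, any t
  wgt2 <- retinex_weight(to_log(make_img(array(0.5, c(8, 8, 3)))), t = 1e-6)
  expect_true(all(wgt2 == 100))
  expect_error(retinex_weight(to_log(make_img(px)), t = 0), "t must be")
  # colour pooling: an edge in one channel suffices
  px3 <- array(0.3, c(8, 8, 3))
  px3[, 5:8, 2] <- 0.3 * exp(0.5)
  expect_equal(retinex_weight(to_log(make_img(px3)), t = 0.1)[3, 4], 0)
})

test_that("scale_indicator flags pixels within 95% of the brightest", {
  # linear ramp over 100 columns: exactly the columns >= 0.95 flagged
  ramp <- matrix(rep(seq(0.01, 1, length.out = 100), each = 8), 8, 100)
  b <- scale_indicator(make_img(array(ramp, c(8, 100, 1))), 0.95)
  flagged_cols <- which(colSums(b) > 0)
  expect_identical(flagged_cols, which(seq(0.01, 1, length.out = 100) >= 0.95))
  expect_length(flagged_cols, 6)
  expect_true(all(b %in% c(0, 1)))
  # uniform image: everything is the max
  expect_true(all(scale_indicator(make_img(array(0.4, c(8, 8, 3)))) == 1))
  # brightness is the max over channels
  px <- array(0.2, c(8, 8, 3))
  px[1, 1, 2] <- 1
  b3 <- scale_indicator(make_img(px))
  expect_equal(sum(b3), 1)
  expect_equal(b3[1, 1], 1)
})

test_that("texture_pairs links identical texture and ignores flat/noise", {
  set.seed(42)
  # two identical noisy patches on a flat background, far apart
  px <- matrix(0.5, 24, 24)
  tex <- matrix(runif(25, 0.1, 0.9), 5, 5)
  px[3:7, 3:7] <- tex
  px[17:21, 17:21] <- tex
  img <- make_img(array(px, c(24, 24, 1)))
  cfg <- decomposition_config(texture_stride = 1L, texture_corr_min = 0.95)
  tp <- texture_pairs(to_log(img), full_mask(24, 24), cfg)
  h <- 24
  c1 <- (5 - 1) * h + 5; c2 <- (19 - 1) * h + 19
  expect_true(any(tp$i == min(c1, c2) & tp$j == max(c1, c2)))
  expect_true(all(tp$i != tp$j))
  expect_true(all(tp$weight > 0))

  # pure noise with corr_min = 1 -> empty
  pnoise <- make_img(array(runif(24 * 24, 0.1, 0.9), c(24, 24, 1)))
  tp2 <- texture_pairs(to_log(pnoise), full_mask(24, 24),
                       decomposition_config(texture_corr_min = 1.0))
  expect_length(tp2$i, 0)

  # flat image has no texture at all
  tp3 <- texture_pairs(to_log(make_img(array(0.5, c(24, 24, 1)))),
                       full_mask(24, 24), decomposition_config())
  expect_length(tp3$i, 0)
})

test_that("texture_pairs matches the brute-force oracle on a checkerboard", {
  chk <- outer(0:27, 0:27, function(y, x) {
    ifelse(((x %/% 2) + (y %/% 2)) %% 2 == 0, 0.2, 0.8)
  })
  img <- make_img(array(chk, c(28, 28, 1)))
  cfg <- decomposition_config(texture_stride = 2L, texture_knn = 4L,
                              texture_corr_min = 0.9)
  got <- texture_pairs(to_log(img), full_mask(28, 28), cfg)
  gotm <- cbind(got$i, got$j)
  gotm <- gotm[order(gotm[, 1], gotm[, 2]), , drop = FALSE]
  ref <- oracle_texture_pairs(to_log(img), full_mask(28, 28), cfg)
  expect_equal(unname(gotm), unname(ref))
  expect_gt(nrow(ref), 0)
})

test_that("decompose solves the uniform image exactly", {
  img <- make_img(array(0.5, c(8, 8, 3)))
  d <- decompose(img, full_mask(8, 8))
  expect_lt(max(abs(d$shading - 1)), 1e-8)
  expect_lt(max(abs(d$reflectance - 0.5)), 1e-8)
  # reconstruction identity holds by construction
  lg <- to_log(img)$log_pixels
  for (ch in 1:3) {
    expect_lt(max(abs(log(d$reflectance[, , ch]) + log(d$shading) -
                        lg[, , ch])), 1e-10)
  }
})

test_that("decompose agrees with the dense brute-force oracle on small instances", {
  set.seed(9)
  for (trial in 1:2) {
    n <- c(8L, 12L)[trial]
    # smooth shading x 2-patch reflectance
    x <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
    s_true <- 0.6 + 0.3 * x
    r_true <- matrix(0.3, n, n); r_true[, seq_len(n / 2)] <- 0.8
    px <- array(pmin(r_true * s_true, 1), c(n, n, 1))
    img <- make_img(px)
    msk <- if (trial == 2) {
      mm <- matrix(TRUE, n, n); mm[1, 1] <- FALSE; region_mask(mm)
    } else full_mask(n, n)
    cfg <- decomposition_config(lambda_tx = 0)
    got <- decompose(img, msk, cfg)
    ref <- oracle_dense_decompose(img, msk, cfg)
    expect_lt(max(abs(got$log_shading[msk$inside] - ref[msk$inside])), 1e-6)
  }
})

test_that("decompose recovers smooth shading under a Mondrian pattern", {
  size <- c(64L, 64L)
  hgt <- make_height_field("curled_sheet", size,
                           list(amplitude = 8, start_frac = 0.4))
  refl <- make_reflectance("mondrian", size, list(n_patches = 6L), seed = 3)
  sc <- render_scene(hgt, refl, light_direction(0), ambient = 0.1, seed = 3)
  d <- decompose(sc$rendered, sc$mask)
  m <- sc$mask$inside
  D <- sc$light$vector
  lam <- D[1] * sc$true_normals[, , 1] + D[2] * sc$true_normals[, , 2] +
    D[3] * sc$true_normals[, , 3]
  s_true <- pmax(lam, 0) + sc$ambient
  expect_gt(stats::cor(log(d$shading[m]), log(s_true[m])), 0.9)

  # recovered strong reflectance gradients sit on true patch borders
  lr_mean <- apply(log(pmax(d$reflectance, 1e-4)), c(1, 2), mean)
  g <- pictodepth:::grad_forward(lr_mean)
  rec_edge <- m & (sqrt(g$gx^2 + g$gy^2) > 0.1)
  gt <- pictodepth:::grad_forward(log(refl[, , 1]))
  true_edge <- abs(gt$gx) > 1e-9 | abs(gt$gy) > 1e-9
  dil <- true_edge
  for (dr in -1:1) for (dc in -1:1) {
    sh <- matrix(FALSE, size[1], size[2])
    rs <- max(1, 1 + dr):min(size[1], size[1] + dr)
    cs <- max(1, 1 + dc):min(size[2], size[2] + dc)
    sh[rs, cs] <- true_edge[rs - dr, cs - dc]
    dil <- dil | sh
  }
  expect_gte(sum(rec_edge & dil) / sum(rec_edge), 0.9)
})

test_that("global intensity scaling is absorbed as the scale constraint dictates", {
  # Sc pins log S = 0 at the brightest pixels, so S is invariant to a
  # global scaling with identical b support and R carries the factor.
  size <- c(32L, 32L)
  hgt <- make_height_field("curled_sheet", size, list(amplitude = 4))
  refl <- make_reflectance("uniform", size, list(value = 0.9))
  sc <- render_scene(hgt, refl, light_direction(0), ambient = 0.1)
  img1 <- sc$rendered
  img2 <- radiance_image(img1$pixels / 2)
  msk <- full_mask(32, 32)
  d1 <- decompose(img1, msk)
  d2 <- decompose(img2, msk)
  expect_lt(max(abs(d1$log_shading - d2$log_shading)), 1e-6)
  expect_lt(max(abs(d2$reflectance - d1$reflectance / 2)), 1e-6)
})

test_that("decompose rejects an all-black masked region", {
  px <- array(0.5, c(8, 8, 1))
  px[3:6, 3:6, 1] <- 0
  mm <- matrix(FALSE, 8, 8); mm[3:6, 3:6] <- TRUE
  expect_error(decompose(make_img(px), region_mask(mm)), "all black")
})

test_that("decomposition_config validates its invariants", {
  expect_error(decomposition_config(lambda_rx = -1), "weights")
  expect_error(decomposition_config(brightness_quantile = 1), "quantile")
  expect_error(decomposition_config(texture_patch_px = 4), "odd")
})
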