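test_that("images round-trip bit-exactly through PNG and TIFF", {
  set.seed(11)
  for (depth in c(8L, 16L)) {
    maxv <- 2^depth - 1
    for (nch in c(1L, 3L)) {
      px <- array(sample(0:maxv, 16 * 12 * nch, replace = TRUE),
                  c(12, 16, nch))
      for (ext in c("png", "tif")) {
        f <- withr::local_tempfile(fileext = paste0(".", ext))
        write_image(px, f, bit_depth = depth, already_quantized = TRUE)
        back <- if (ext == "png") pictodepth:::read_png(f)
                else pictodepth:::read_tiff(f)
        expect_identical(back$bit_depth, depth)
        expect_true(all(back$pixels == px))
        # second round trip is byte-identical on disk
        f2 <- withr::local_tempfile(fileext = paste0(".", ext))
        write_image(back$pixels, f2, bit_depth = depth,
                    already_quantized = TRUE)
        expect_identical(readBin(f, "raw", file.size(f)),
                         readBin(f2, "raw", file.size(f2)))
      }
    }
  }
})

test_that("load_image scales by bit depth and drops nothing it shouldn't", {
  f <- withr::local_tempfile(fileext = ".png")
  px <- matrix(c(0L, 255L, 128L, 64L), 2, 2)
  big <- matrix(0L, 8, 8); big[1:2, 1:2] <- px
  write_image(big, f, bit_depth = 8L, already_quantized = TRUE)
  img <- load_image(f, linearize_srgb = FALSE)
  expect_equal(img$pixels[1, 1, 1], 0)
  expect_equal(img$pixels[2, 1, 1], 1)
  expect_equal(img$pixels[1, 2, 1], 128 / 255)

  f16 <- withr::local_tempfile(fileext = ".png")
  big16 <- matrix(0L, 8, 8); big16[1, 1] <- 32768L
  write_image(big16, f16, bit_depth = 16L, already_quantized = TRUE)
  img16 <- load_image(f16, linearize_srgb = FALSE)
  expect_equal(img16$pixels[1, 1, 1], 32768 / 65535, tolerance = 1e-12)
  expect_error(load_image(f16, bit_depth_hint = 8L), "bit depth mismatch")

  # sRGB linearization applies the standard transfer
  imgL <- load_image(f, linearize_srgb = TRUE)
  expect_equal(imgL$pixels[1, 2, 1], srgb_to_linear(128 / 255))
  # and the transfer pair inverts
  v <- seq(0, 1, by = 0.05)
  expect_equal(linear_to_srgb(srgb_to_linear(v)), v, tolerance = 1e-12)

  expect_error(load_image(withr::local_tempfile(fileext = ".png")),
               "no such file")
})

test_that("JPEG input is detected and refused with a clear message", {
  f <- withr::local_tempfile(fileext = ".jpg")
  writeBin(as.raw(c(0xff, 0xd8, 0xff, 0xe0, rep(0, 16))), f)
  expect_error(load_image(f), "JPEG")
})

test_that("load_mask handles nonzero-inside, fragmentation and errors", {
  img <- radiance_image(array(0.5, c(10, 10, 1)))
  f <- withr::local_tempfile(fileext = ".png")

  write_image(matrix(255L, 10, 10), f, already_quantized = TRUE)
  expect_true(all(load_mask(f, img)$inside))

  # two disjoint blobs: larger kept with a warning
  mm <- matrix(0L, 10, 10)
  mm[2:6, 2:6] <- 7L      # 25 px, any nonzero counts
  mm[9:10, 9:10] <- 255L  # 4 px
  write_image(mm, f, already_quantized = TRUE)
  expect_warning(msk <- load_mask(f, img), "disconnected")
  expect_equal(sum(msk$inside), 25)
  expect_true(all(which(msk$inside) %in% which(mm == 7L)))

  write_image(matrix(0L, 10, 10), f, already_quantized = TRUE)
  expect_error(suppressWarnings(load_mask(f, img)), "empty")

  write_image(matrix(255L, 9, 10), f, already_quantized = TRUE)
  expect_error(load_mask(f, img), "does not match")
})

test_that("to_log clamps, inverts and is monotone", {
  img <- radiance_image(array(seq(0, 1, length.out = 64), c(8, 8, 1)))
  lg <- to_log(img, eps_floor = 1e-4)
  expect_equal(max(lg$log_pixels), 0)           # log(1)
  expect_equal(min(lg$log_pixels), log(1e-4))   # clamped black
  above <- img$pixels >= 1e-4
  expect_equal(exp(lg$log_pixels[above]), img$pixels[above], tolerance = 1e-12)
  v <- sort(img$pixels[above])
  expect_true(all(diff(log(v)) >= 0))
  expect_error(to_log(img, eps_floor = 0), "eps_floor")
  expect_error(to_log(img, eps_floor = -1), "eps_floor")
})

test_that("normal-map encoding follows the RGB convention and round-trips", {
  mask <- region_mask(matrix(TRUE, 8, 8))
  n <- array(0, c(8, 8, 3)); n[, , 3] <- 1
  n[1, 1, ] <- c(1, 0, 0)
  enc <- encode_normal_map(n, mask)
  expect_identical(enc[2, 2, ], c(128L, 128L, 255L))
  expect_identical(enc[1, 1, ], c(255L, 128L, 0L))
  # quantization roundtrip within 1/255 per channel
  set.seed(5)
  v <- matrix(rnorm(64 * 3), 64, 3)
  v <- v / sqrt(rowSums(v^2))
  v[, 3] <- abs(v[, 3])
  v <- v / sqrt(rowSums(v^2))
  nr <- array(0, c(8, 8, 3))
  for (k in 1:3) nr[, , k] <- matrix(v[, k], 8, 8)
  dec <- decode_normal_map(encode_normal_map(nr, mask))
  expect_lt(max(abs(dec[, , 1] - nr[, , 1])), 1 / 255 + 1e-12)
  expect_lt(max(abs(dec[, , 2] - nr[, , 2])), 1 / 255 + 1e-12)
  expect_lt(max(abs(dec[, , 3] - nr[, , 3])), 1 / 255 + 1e-12)
  # outside mask zeroed
  m2 <- matrix(TRUE, 8, 8); m2[1, ] <- FALSE
  enc2 <- encode_normal_map(n, region_mask(m2))
  expect_true(all(enc2[1, , ] == 0L))
})

test_that("height-map encoding is min-max with the constant convention", {
  mask <- region_mask(matrix(TRUE, 8, 8))
  hgt <- matrix(0, 8, 8); hgt[1, 1:3] <- c(0, 1, 2)
  enc <- encode_height_map(hgt, mask)
  expect_identical(enc[1, 1:3], c(0L, 128L, 255L))
  expect_identical(encode_height_map(matrix(7, 8, 8), mask),
                   matrix(128L, 8, 8))
  two <- matrix(-5, 8, 8); two[1, 1] <- 5
  enc2 <- encode_height_map(two, mask)
  expect_identical(enc2[1, 1], 255L)
  expect_identical(enc2[2, 2], 0L)
  # affine invariance: same raster for a*H + b, a > 0
  set.seed(2)
  hr <- matrix(runif(64), 8, 8)
  expect_identical(encode_height_map(hr, mask),
                   encode_height_map(3.7 * hr + 11, mask))
  # outside mask is 0
  m2 <- matrix(TRUE, 8, 8); m2[, 8] <- FALSE
  expect_true(all(encode_height_map(hr, region_mask(m2))[, 8] == 0L))
})

test_that("region_mask validates and repairs; radiance_image validates", {
  expect_error(region_mask(matrix(FALSE, 4, 4)), "no inside")
  frag <- matrix(FALSE, 6, 6); frag[1:2, 1:2] <- TRUE; frag[5:6, 5:6] <- TRUE
  expect_error(region_mask(frag), "components")
  expect_warning(rm2 <- region_mask(frag, repair = TRUE), "disconnected")
  expect_equal(sum(rm2$inside), 4)

  expect_error(radiance_image(array(0.5, c(4, 8, 1))), "at least 8 x 8")
  expect_error(radiance_image(array(2, c(8, 8, 1))), "\\[0, 1\\]")
  expect_error(radiance_image(array(NA_real_, c(8, 8, 1))), "finite")
})

test_that("PLY export writes a valid masked vertex grid", {
  m <- matrix(FALSE, 8, 8); m[2:6, 2:7] <- TRUE
  mask <- region_mask(m)
  hgt <- matrix(seq_len(64) / 10, 8, 8)
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(hgt, mask, f)
  lines <- readLines(f)
  expect_identical(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("element face", lines, value = TRUE)))
  expect_equal(nv, sum(m))
  expect_equal(nf, 2 * 5 * 4)  # all interior quads full: (5-1)x(6-1) quads x2
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  expect_length(body, nv + nf)
  face_tok <- strsplit(body[(nv + 1):(nv + nf)], " ")
  expect_true(all(vapply(face_tok, function(tk) {
    idx <- as.integer(tk[-1])
    tk[1] == "3" && all(idx >= 0) && all(idx < nv)
  }, logical(1))))
})
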