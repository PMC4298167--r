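test_that("grayscale conversion applies standard luminance weights", {
  mk <- function(r, g, b) {
    a <- array(0, dim = c(64, 64, 3))
    a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
    a
  }
  expect_true(all(to_grayscale(mk(255, 255, 255))$pixels == 255))
  expect_true(all(to_grayscale(mk(0, 0, 0))$pixels == 0))
  # luminance oracle computed independently: 0.299*100 + 0.587*150 + 0.114*200
  expected <- floor(0.299 * 100 + 0.587 * 150 + 0.114 * 200 + 0.5)
  expect_equal(expected, 141)
  expect_true(all(to_grayscale(mk(100, 150, 200))$pixels == expected))
})

test_that("images load from PNG and TIFF with depth normalization", {
  d <- withr::local_tempdir()
  # 8-bit grayscale PNG: identity
  set.seed(31)
  m <- matrix(sample(0:255, 128 * 96, replace = TRUE), 96, 128)
  p8 <- file.path(d, "gray8.png")
  png::writePNG(m / 255, p8)
  img <- load_image(p8)
  expect_identical(img$pixels, matrix(as.integer(m), 96, 128))
  expect_equal(c(img$height, img$width), c(96, 128))

  # 16-bit TIFF endpoints: 0 -> 0, 65535 -> 255
  m16 <- matrix(0, 64, 64); m16[1, 1] <- 65535; m16[2, 2] <- 32768
  p16 <- file.path(d, "gray16.tif")
  tiff::writeTIFF(m16 / 65535, p16, bits.per.sample = 16L)
  img16 <- load_image(p16)
  expect_equal(img16$pixels[1, 1], 255L)
  expect_equal(img16$pixels[3, 3], 0L)

  # RGB PNG: converted via luminance
  a <- array(0, dim = c(64, 64, 3))
  a[, , 1] <- 100 / 255; a[, , 2] <- 150 / 255; a[, , 3] <- 200 / 255
  prgb <- file.path(d, "rgb.png")
  png::writePNG(a, prgb)
  expect_true(all(load_image(prgb)$pixels == 141L))

  # rejections name the file
  expect_error(load_image(file.path(d, "missing.png")), "missing.png")
  small <- file.path(d, "small.png")
  png::writePNG(matrix(0.5, 32, 32), small)
  expect_error(load_image(small), "small")
})

test_that("gaussian smoothing preserves constants, dimensions and mass", {
  const <- calibrated_image(matrix(80L, 64, 64))
  expect_identical(gaussian_smooth(const, 3)$pixels, const$pixels)
  img <- random_image(11)
  expect_identical(gaussian_smooth(img, 0), img)
  sm <- gaussian_smooth(img, 2)
  expect_equal(dim(sm$pixels), dim(img$pixels))
  expect_true(all(sm$pixels >= 0 & sm$pixels <= 255))
  # impulse response: total mass conserved within quantization, and the
  # response matches direct kernel summation
  m <- matrix(0L, 65, 65); m[33, 33] <- 255L
  out <- gaussian_smooth(calibrated_image(m), 2)$pixels
  k <- gaussian_kernel(2)
  expect_lt(abs(sum(out) - 255), 0.5 * sum(k * 255 >= 0.5) + 1)
  half <- (nrow(k) - 1) / 2
  expected <- floor(255 * k + 0.5)
  got <- out[(33 - half):(33 + half), (33 - half):(33 + half)]
  expect_true(all(abs(got - expected) <= 1))
  expect_error(gaussian_smooth(img, -1), "sigma")
})

test_that("contrast enhancement stretches quantiles and is monotone", {
  m <- matrix(10L, 64, 64); m[1:32, ] <- 200L
  out <- enhance_contrast(calibrated_image(m), 0)$pixels
  expect_equal(sort(unique(as.vector(out))), c(0L, 255L))
  expect_true(all(out[m == 10] == 0) && all(out[m == 200] == 255))

  const <- calibrated_image(matrix(99L, 64, 64))
  expect_identical(enhance_contrast(const, 0.1)$pixels, const$pixels)

  # quantile oracle by sorting all pixels of a ramp
  ramp <- calibrated_image(matrix(rep(0:255, each = 16), 64, 64))
  s <- sort(as.vector(ramp$pixels)); n <- length(s)
  lo <- s[floor(0.1 * n) + 1]; hi <- s[ceiling(0.9 * n)]
  out <- enhance_contrast(ramp, 0.1)$pixels
  expect_true(all(out[ramp$pixels < lo] == 0))
  expect_true(all(out[ramp$pixels > hi] == 255))
  mid <- ramp$pixels >= lo & ramp$pixels <= hi
  expect_true(all(abs(out[mid] - (ramp$pixels[mid] - lo) / (hi - lo) * 255) <= 0.5))

  # monotonicity on random images
  for (seed in 1:5) {
    img <- random_image(seed)
    out <- enhance_contrast(img, 0.02)$pixels
    o <- order(as.vector(img$pixels))
    expect_true(all(diff(out[o]) >= 0))
  }
})

test_that("binarization thresholds strictly above, inverts brightfield, matches Otsu oracle", {
  ramp <- calibrated_image(matrix(rep(0:255, each = 16), 64, 64))
  mask <- binarize(ramp, threshold_override = 128)
  expect_identical(unclass(mask)[, ], ramp$pixels >= 129)
  expect_equal(attr(mask, "threshold"), 128L)

  # automatic threshold on a bimodal image lies between the modes and
  # equals the exhaustive between-class-variance oracle
  set.seed(5)
  v <- pmin(pmax(round(c(rnorm(2048, 40, 5), rnorm(2048, 200, 5))), 0), 255)
  bim <- calibrated_image(matrix(as.integer(v), 64, 64))
  mask <- binarize(bim)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 60); expect_lt(thr, 180)
  expect_equal(thr, brute_force_otsu(bim$pixels))
  for (seed in 1:6) {
    img <- random_image(seed, 64, 80)
    expect_equal(attr(binarize(img), "threshold"),
                 brute_force_otsu(img$pixels))
  }

  # brightfield of the inverted image gives the identical mask
  inv <- calibrated_image(255L - bim$pixels, modality = "brightfield")
  expect_identical(as.vector(binarize(inv)), as.vector(binarize(bim)))

  blank <- calibrated_image(matrix(0L, 64, 64))
  expect_true(attr(binarize(blank), "degenerate"))
})

test_that("selection smoothing is a closing: superset, fills notches, identity at 0", {
  rr <- matrix(1:64, 64, 64); cc <- t(rr)
  disk <- (rr - 32)^2 + (cc - 32)^2 <= 20^2
  expect_identical(smooth_selection(disk, 0), disk)
  # closing a convex disk changes (almost) nothing
  expect_lt(sum(xor(smooth_selection(disk, 4), disk)), 10)
  # a 1-px radial notch is filled; oracle by direct dilate-then-erode
  notched <- disk; notched[32, 33:52] <- FALSE
  sm <- smooth_selection(notched, 2)
  br <- EBImage::makeBrush(5, "disc")
  oracle <- EBImage::erode(EBImage::dilate(EBImage::Image(t(notched * 1)), br), br)
  expect_identical(unclass(sm)[, ], t(EBImage::imageData(oracle)) > 0.5)
  expect_true(all(sm[32, 36:49]))
  # closing never removes foreground
  for (seed in 1:5) {
    set.seed(seed)
    blob <- matrix(runif(64 * 64) > 0.6, 64, 64)
    blob[c(1:6, 59:64), ] <- FALSE; blob[, c(1:6, 59:64)] <- FALSE
    expect_true(all(blob <= smooth_selection(blob, 3)))
  }
})
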