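test_that("fuse_min is commutative, associative, idempotent and takes minima", {
  a <- random_image(1)
  b <- random_image(2)
  c <- random_image(3)
  expect_identical(unclass(fuse_min(a, b)), unclass(fuse_min(b, a)))
  expect_identical(unclass(fuse_min(fuse_min(a, b), c)),
                   unclass(fuse_min(a, fuse_min(b, c))))
  expect_identical(unclass(fuse_min(a, a)), unclass(a))

  lo <- raster_image(matrix(10, 5, 5), 0.13)
  hi <- raster_image(matrix(20, 5, 5), 0.13)
  expect_true(all(unclass(fuse_min(lo, hi)) == 10))
  expect_identical(mm_per_px(fuse_min(lo, hi)), 0.13)
  expect_error(fuse_min(a, raster_image(matrix(0, 3, 3), 0.13)), "shape")
})

test_that("one-sided specular blobs do not survive minimum-tonal fusion", {
  base <- matrix(50, 80, 80)
  left <- base; left[10:20, 10:20] <- 255
  right <- base; right[50:60, 50:60] <- 255
  fused <- fuse_min(raster_image(left, 0.13), raster_image(right, 0.13))
  expect_lte(max(unclass(fused)), 50)
})

test_that("estimate_flatfield recovers smooth backgrounds and rejects thin roots", {
  uni <- raster_image(matrix(120, 60, 60), 0.13)
  m <- estimate_flatfield(uni, 31)
  expect_lte(max(abs(m$background - 120)), 1)
  expect_true(all(m$background > 0))

  withroots <- matrix(100, 80, 80)
  withroots[, c(20, 21, 22, 55, 56, 57)] <- 200
  m2 <- estimate_flatfield(raster_image(withroots, 0.13), 31)
  under <- m2$background[, c(20:22, 55:57)]
  expect_true(all(under >= 95 & under <= 110))

  ramp <- matrix(rep(seq(50, 150, length.out = 200), each = 120), 120, 200)
  m3 <- estimate_flatfield(raster_image(ramp, 0.13), 31)
  expect_lte(max(abs(m3$background - ramp)), 5)

  expect_error(estimate_flatfield(uni, 5), "kernel_scale")
  expect_error(estimate_flatfield(uni, 100), "exceeds")
})

test_that("correct_illumination flattens vignetting and preserves local contrast", {
  ramp <- matrix(rep(seq(50, 150, length.out = 200), each = 120), 120, 200)
  rimg <- raster_image(ramp, 0.13)
  model <- estimate_flatfield(rimg, 31)
  flat <- correct_illumination(rimg, model)
  expect_lt(sd(unclass(flat)), 0.1 * sd(ramp))
  expect_equal(mean(unclass(flat)), mean(ramp), tolerance = 0.02)

  selfm <- structure(list(background = ramp, method = "given", kernel_scale = NA),
                     class = "flatfield_model")
  const <- correct_illumination(rimg, selfm)
  expect_lte(sd(unclass(const)), 1)

  scene <- ramp
  scene[, c(60, 61, 62)] <- scene[, c(60, 61, 62)] + 80  # roots riding the ramp
  simg <- raster_image(scene, 0.13)
  corrected <- correct_illumination(simg, estimate_flatfield(simg, 31))
  before <- scene[60, 61] / scene[60, 66]
  after <- unclass(corrected)[60, 61] / unclass(corrected)[60, 66]
  expect_equal(after, before, tolerance = 0.05)
})

test_that("to_gray extracts channels and flags impossible requests", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(200, 10, 30)
  px[2, 2, ] <- c(30, 60, 90)
  img <- raster_image(px, 0.13)
  expect_identical(unclass(to_gray(img, "red"))[1, 1], 200)
  expect_identical(unclass(to_gray(img, "mean"))[2, 2], 60)
  gray <- raster_image(matrix(5, 2, 2), 0.13)
  expect_error(to_gray(gray, "red"), "channel")
  expect_identical(unclass(to_gray(gray, "mean")), unclass(gray))
})

test_that("red channel separates roots from blue paper better than blue channel", {
  # blue paper: bright blue, dim red; root: reflects evenly (red-bright vs paper)
  nr <- 60; nc <- 60
  red <- matrix(60, nr, nc); blue <- matrix(200, nr, nc)
  rootcols <- 28:32
  red[, rootcols] <- 120; blue[, rootcols] <- 150
  img <- raster_image(array(c(red, matrix(100, nr, nc), blue), c(nr, nc, 3)), 0.13)
  contrast <- function(ch) {
    m <- unclass(to_gray(img, ch))
    abs(mean(m[, rootcols]) - mean(m[, -rootcols]))
  }
  expect_gt(contrast("red"), contrast("blue"))
})

test_that("preprocess removes one-sided glare and reduces to the red channel", {
  expect_true({
    uni <- gray_to_rgb(raster_image(matrix(80, 50, 50), 0.13))
    out <- preprocess(uni, uni, kernel_scale = 25)
    sd(unclass(out)) <= 1
  })

  cfg <- render_config()
  rr <- render(straight_system(diameter = 0.9), cfg)
  base <- unclass(rr$image)
  left <- base; left[60:75, 60:75] <- 255    # glare only in the left image
  right <- base; right[300:315, 300:315] <- 255
  out <- preprocess(gray_to_rgb(raster_image(left, 0.13)),
                    gray_to_rgb(raster_image(right, 0.13)), kernel_scale = 75)
  rootcols <- 200:260
  outside <- unclass(out)[, -rootcols]
  expect_lte(max(outside), cfg$background_level + 3)

  clean <- gray_to_rgb(rr$image)
  ident <- preprocess(clean, clean, channel = "red", kernel_scale = 75)
  expect_lte(max(abs(unclass(ident) - base)), 1)
  expect_identical(mm_per_px(ident), mm_per_px(rr$image))
})
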