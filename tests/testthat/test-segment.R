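test_that("global_threshold applies the strict comparison rule", {
  img <- raster_image(matrix(c(5, 200, 100, 255), 2, 2), 0.13)
  m <- global_threshold(img, 100, "root_dark")
  expect_true(m[1, 1])          # 5 below the threshold -> root
  expect_false(m[2, 1])         # 200 above -> background
  expect_false(m[1, 2])         # equal to t -> background
  expect_false(any(global_threshold(img, 0, "root_dark")))
  m255 <- global_threshold(img, 255, "root_dark")
  expect_identical(matrix(as.logical(m255), 2, 2),
                   matrix(unclass(img) < 255, 2, 2))
  expect_error(global_threshold(img, 300, "root_dark"), "threshold")
})

test_that("auto_threshold maximizes between-class variance (brute-force oracle)", {
  two <- raster_image(matrix(c(rep(50, 90), rep(200, 10)), 10, 10), 0.13)
  t2 <- auto_threshold(two)
  expect_gt(t2, 50)
  expect_lt(t2, 200)

  img <- random_image(5, 30, 30)
  t <- auto_threshold(img)
  v <- as.numeric(unclass(img))
  oracle <- function(k) {                 # split {<= k} vs {> k}
    lo <- v[v <= k]; hi <- v[v > k]
    if (!length(lo) || !length(hi)) return(-Inf)
    (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
  }
  scores <- vapply(0:254, oracle, numeric(1))
  expect_equal(t, (0:254)[which.max(scores)] + 0.5)

  expect_error(auto_threshold(raster_image(matrix(7, 4, 4), 0.13)), "constant")
})

test_that("adaptive_threshold matches hand-computed block means", {
  uni <- raster_image(matrix(123, 50, 50), 0.13)
  expect_false(any(adaptive_threshold(uni, 16, 0.05)))

  img <- matrix(100, 100, 100)
  img[, 41:43] <- 200                     # 3-px root crossing blocks of 32
  m <- adaptive_threshold(raster_image(img, 0.13), 32, 0.2, "root_bright")
  # block mean in root blocks: (3*32*200 + 29*32*100) / 1024 = 109.375
  # root deviation 90.6 > 51 = 0.2 * 255; background deviation below 0
  expect_true(all(m[, 41:43]))
  expect_false(any(m[, -(41:43)]))

  expect_error(adaptive_threshold(uni, 2, 0.1), "block_size")
  expect_error(adaptive_threshold(uni, 200, 0.1), "exceeds")
  expect_error(adaptive_threshold(uni, 16, 0), "proportion")
})

test_that("adaptive thresholding beats any global threshold under a gradient", {
  nr <- 200; nc <- 200
  bg <- matrix(rep(seq(50, 150, length.out = nc), each = nr), nr, nc)
  rootcols <- c(40:42, 100:102, 160:162)
  img <- bg; img[, rootcols] <- img[, rootcols] + 80
  truth <- matrix(FALSE, nr, nc); truth[, rootcols] <- TRUE
  gray <- raster_image(img, 0.13)

  ad <- adaptive_threshold(gray, 32, 0.2, "root_bright")
  expect_gte(sum(ad & truth) / sum(truth), 0.95)
  expect_lte(sum(ad & !truth) / sum(!truth), 0.01)

  worst_global <- min(vapply(0:255, function(t) {
    g <- unclass(img) > t
    sum(g != truth)
  }, numeric(1)))
  expect_gt(worst_global, 0.05 * sum(truth))   # every single t misclassifies
})

test_that("double_adaptive_threshold keeps thin roots and drops wide plateaus", {
  uni <- raster_image(matrix(50, 80, 80), 0.13)
  expect_false(any(double_adaptive_threshold(uni)))

  img <- matrix(100, 120, 120)
  img[, 60:62] <- 200
  m <- double_adaptive_threshold(raster_image(img, 0.13), c(5, 15, 31), 0.1)
  expect_true(all(m[, 61]))               # centerline pixels survive

  wide <- matrix(100, 120, 220)
  wide[, 60:160] <- 200                   # plateau much wider than 31 px
  mw <- double_adaptive_threshold(raster_image(wide, 0.13), c(5, 15, 31), 0.1)
  expect_false(any(mw[, 80:140]))         # interior sees no mean change
  expect_true(any(mw[, c(58:64, 156:162)]))  # edges do

  expect_error(double_adaptive_threshold(uni, c(15, 5), 0.1), "increasing")
  expect_error(double_adaptive_threshold(uni, 15, 0.1), "increasing|sizes")
})

test_that("thresholds are monotone in their tuning parameter", {
  img <- random_image(8, 60, 60)
  masks <- lapply(c(60, 120, 180), function(t) global_threshold(img, t, "root_dark"))
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))

  amasks <- lapply(c(0.1, 0.2, 0.4), function(p) adaptive_threshold(img, 16, p))
  expect_true(all(amasks[[2]] <= amasks[[1]]))
  expect_true(all(amasks[[3]] <= amasks[[2]]))
})

test_that("root_dark on an image equals root_bright on its negative", {
  img <- random_image(9, 50, 50)
  neg <- raster_image(255 - unclass(img), mm_per_px(img))
  expect_identical(unclass(global_threshold(img, 80, "root_dark")),
                   unclass(global_threshold(neg, 175, "root_bright")))
  expect_identical(unclass(adaptive_threshold(img, 16, 0.15, "root_dark")),
                   unclass(adaptive_threshold(neg, 16, 0.15, "root_bright")))
  expect_identical(
    unclass(double_adaptive_threshold(img, c(5, 11, 21), 0.08, "root_dark")),
    unclass(double_adaptive_threshold(neg, c(5, 11, 21), 0.08, "root_bright")))
})

test_that("every method recovers noiseless rendered roots above half-amplitude", {
  cfg <- render_config()
  rr <- render(straight_system(diameter = 0.6), cfg)
  img <- rr$image
  half <- cfg$background_level + cfg$foreground_amplitude / 2
  truth <- unclass(img) > half
  score <- function(mask) c(recall = sum(mask & truth) / sum(truth),
                            fpr = sum(mask & !truth) / sum(!truth))
  for (mask in list(global_threshold(img, half, "root_bright"),
                    adaptive_threshold(img, 64, 0.1, "root_bright"),
                    double_adaptive_threshold(img, c(9, 19, 39), 0.1, "root_bright"))) {
    s <- score(unclass(mask))
    expect_gte(s[["recall"]], 0.99)
    expect_lte(s[["fpr"]], 0.01)
  }
})

test_that("clean_mask removes specks and matches the flood-fill oracle", {
  m <- matrix(FALSE, 40, 40)
  m[5, 5:6] <- TRUE                       # 2-px speck
  m[15:34, 10:34] <- TRUE                 # 500-px root blob
  bm <- binary_mask(m, 0.13)
  cleaned <- clean_mask(bm, 5)
  expect_false(any(cleaned[1:10, 1:10]))
  expect_true(all(cleaned[15:34, 10:34]))

  ws <- get("with_seed", envir = asNamespace("rootraster"))
  noisy <- ws(21, matrix(runif(3600) < 0.3, 60, 60))
  cl <- clean_mask(binary_mask(noisy, 0.13), 5)
  lab <- label_components_oracle(noisy)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= 5)
  expect_identical(sum(cl), sum(sizes[keep]))
  expect_identical(max(label_components_oracle(matrix(as.logical(cl), 60, 60))),
                   length(keep))

  holed <- matrix(FALSE, 20, 20)
  holed[5:15, 5:15] <- TRUE; holed[9:11, 9:11] <- FALSE
  filled <- clean_mask(binary_mask(holed, 0.13), 0, fill_holes = TRUE)
  expect_true(all(filled[5:15, 5:15]))
})
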