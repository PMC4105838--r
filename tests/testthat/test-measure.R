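test_that("skeletonize reduces bars to lines and disks to near-points", {
  bar <- matrix(FALSE, 20, 110)
  bar[9:11, 6:105] <- TRUE
  sk <- skeletonize(binary_mask(bar, 0.13))
  px <- which(sk, arr.ind = TRUE)
  expect_identical(length(unique(px[, 1])), 1L)      # a single row
  expect_gte(nrow(px), 90)
  expect_lte(nrow(px), 100)

  disk <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30)
    if ((i - 15)^2 + (j - 15)^2 <= 100) disk[i, j] <- TRUE
  skd <- which(skeletonize(binary_mask(disk, 0.13)), arr.ind = TRUE)
  expect_lte(max(apply(skd, 2, function(v) diff(range(v)))), 3)

  empty <- skeletonize(binary_mask(matrix(FALSE, 5, 5), 0.13))
  expect_false(any(empty))
  expect_identical(skeleton_length(empty), 0)
})

test_that("skeletons are one pixel wide: no pixel is 8-simple", {
  rs <- generate_root_system(2, 1.5, c(60, 80), seed = 17)
  rr <- render(rs, render_config())
  mask <- clean_mask(adaptive_threshold(rr$image, 64, 0.1, "root_bright"), 20)
  sk <- skeletonize(mask)
  m <- matrix(as.logical(sk), nrow(sk), ncol(sk))
  # re-thinning an already minimal skeleton must be the identity
  expect_identical(matrix(as.logical(skeletonize(binary_mask(m, 0.13))),
                          nrow(m), ncol(m)), m)
})

test_that("prune removes short spurs but keeps main paths and isolated lines", {
  m <- matrix(FALSE, 12, 60)
  m[6, 5:55] <- TRUE
  m[7:9, 20] <- TRUE                     # 3-px spur off a junction
  sk <- structure(m, mm_per_px = 0.13,
                  class = c("skeleton", "binary_mask", "matrix", "array"))
  pruned <- prune(sk, 5)
  expect_false(any(pruned[7:9, 20]))
  expect_true(all(pruned[6, 5:55]))

  expect_identical(unclass(prune(sk, 0)), unclass(sk))
  expect_lte(skeleton_length(prune(sk, 5)), skeleton_length(sk))

  iso <- matrix(FALSE, 10, 10); iso[5, 3:6] <- TRUE   # isolated 4-px line
  isk <- structure(iso, mm_per_px = 0.13,
                   class = c("skeleton", "binary_mask", "matrix", "array"))
  expect_identical(unclass(prune(isk, 10)), unclass(isk))

  rs <- generate_root_system(2, 2, c(60, 80), seed = 19)
  rr <- render(rs, render_config(ragged_edges = TRUE))
  sk2 <- skeletonize(clean_mask(adaptive_threshold(rr$image, 64, 0.1), 20))
  lens <- vapply(c(0, 3, 5, 10), function(k) skeleton_length(prune(sk2, k)),
                 numeric(1))
  expect_true(all(diff(lens) <= 1e-9))   # monotone non-increasing in max_spur_px
})

test_that("skeleton_length counts orthogonal and diagonal steps correctly", {
  h <- matrix(FALSE, 5, 15); h[3, 3:13] <- TRUE      # 11-px horizontal run
  hs <- structure(h, mm_per_px = 0.13,
                  class = c("skeleton", "binary_mask", "matrix", "array"))
  expect_equal(skeleton_length(hs), 10 * 0.13, tolerance = 1e-12)

  d <- matrix(FALSE, 15, 15); for (i in 3:13) d[i, i] <- TRUE  # 11-px diagonal
  ds <- structure(d, mm_per_px = 0.13,
                  class = c("skeleton", "binary_mask", "matrix", "array"))
  expect_equal(skeleton_length(ds), 10 * sqrt(2) * 0.13, tolerance = 1e-12)

  # branched tree skeleton: vertical trunk with two side branches
  tr <- matrix(FALSE, 40, 40)
  tr[5:35, 20] <- TRUE
  for (k in 0:8) tr[15 - k, 20 + k] <- TRUE
  tr[25, 21:30] <- TRUE
  trs <- structure(tr, mm_per_px = 0.13,
                   class = c("skeleton", "binary_mask", "matrix", "array"))
  expect_equal(skeleton_length(trs), chain_length_oracle(trs), tolerance = 1e-9)

  # skeleton thinned from a rendered curved root
  arc <- root_system(list(arc_root(5, 10, pi / 2, centre = c(8, 8))), c(30, 30))
  rr <- render(arc, render_config())
  sk <- skeletonize(clean_mask(adaptive_threshold(rr$image, 64, 0.1), 20))
  expect_equal(skeleton_length(sk), chain_length_oracle(sk), tolerance = 1e-9)
})

test_that("skeleton length is at least the end-to-end Euclidean extent", {
  rs <- straight_system(length_mm = 50, diameter = 0.8)
  rr <- render(rs, render_config())
  mask <- clean_mask(adaptive_threshold(rr$image, 64, 0.1), 20)
  sk <- prune(skeletonize(mask), 5)
  px <- which(sk, arr.ind = TRUE)
  extent_mm <- sqrt(diff(range(px[, 1]))^2 + diff(range(px[, 2]))^2) * 0.13
  expect_gte(skeleton_length(sk), extent_mm)
})

test_that("diameter_map recovers widths of bars, disks and rendered roots", {
  bar <- matrix(FALSE, 20, 60); bar[8:12, 5:56] <- TRUE   # 5 px wide
  bm <- binary_mask(bar, 0.13)
  sk <- skeletonize(bm)
  d <- diameter_map(bm, sk)
  centre <- d[10, 15:45]
  expect_true(all(centre >= 0.59 & centre <= 0.65))

  disk <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40)
    if ((i - 20)^2 + (j - 20)^2 <= 100) disk[i, j] <- TRUE
  dbm <- binary_mask(disk, 1)
  dsk <- binary_mask(matrix(FALSE, 40, 40), 1)
  dsk[20, 20] <- TRUE
  expect_equal(diameter_map(dbm, dsk)[20, 20], 20, tolerance = 0.07)

  cfg <- render_config()
  curved <- root("C", 0L, data.frame(x = c(8, 28, 18), y = c(8, 35, 70),
                                     diameter = 0.8))
  rr <- render(root_system(list(curved), c(60, 80)), cfg)
  half <- cfg$background_level + cfg$foreground_amplitude / 2
  hm <- global_threshold(rr$image, half, "root_bright")
  hsk <- prune(skeletonize(hm), 5)
  dm <- diameter_map(hm, hsk)
  expect_lt(abs(median(dm[!is.na(dm)]) - 0.8), 0.13)   # within one pixel

  sk_out <- binary_mask(matrix(FALSE, 20, 60), 0.13)
  sk_out[1, 1] <- TRUE
  expect_error(diameter_map(bm, sk_out), "outside")
})

test_that("length_by_class partitions total length and splits axile/lateral", {
  bar <- matrix(FALSE, 20, 60); bar[10, 5:56] <- TRUE
  sk <- structure(bar, mm_per_px = 0.13,
                  class = c("skeleton", "binary_mask", "matrix", "array"))
  d <- matrix(NA_real_, 20, 60); d[10, 5:56] <- 0.3
  rep <- length_by_class(sk, d, class_edges = 0.5)
  expect_equal(rep$lateral_length, rep$total_length)
  expect_identical(rep$axile_length, 0)
  expect_equal(sum(rep$length_by_class), rep$total_length, tolerance = 0.005)

  # two rendered roots of equal length, one lateral-thin and one axile-thick
  cfg <- render_config()
  thin <- root("L", 0L, data.frame(x = c(15, 15), y = c(5, 75), diameter = 0.3))
  thick <- root("A", 0L, data.frame(x = c(45, 45), y = c(5, 75), diameter = 0.9))
  rr <- render(root_system(list(thin, thick), c(60, 80)), cfg)
  half <- cfg$background_level + cfg$foreground_amplitude / 2
  mask <- global_threshold(rr$image, half, "root_bright")
  mrep <- measure_mask(mask, prune_px = 5, class_edges = 0.5)
  expect_equal(mrep$lateral_length, 70, tolerance = 0.05 * 70)
  expect_equal(mrep$axile_length, 70, tolerance = 0.05 * 70)
  expect_equal(sum(mrep$length_by_class), mrep$total_length, tolerance = 0.005)

  expect_error(length_by_class(sk, d, class_edges = c(0.5, 0.3)), "increasing")
})

test_that("surface_volume follows the cylinder model and its scaling laws", {
  one <- data.frame(length = 10, diameter = 1)
  sv <- surface_volume(one)
  expect_equal(sv$surface, pi * 10)
  expect_equal(sv$volume, pi * 0.25 * 10)
  two <- data.frame(length = 10, diameter = 2)
  sv2 <- surface_volume(two)
  expect_equal(sv2$surface / sv$surface, 2)
  expect_equal(sv2$volume / sv$volume, 4)
})

test_that("resolution helpers reproduce the imaging-setup arithmetic", {
  expect_equal(round(resolution_mm_per_px(490, 3744), 2), 0.13)
  expect_equal(min_detectable_diameter(0.13, 3), 0.39)
  expect_equal(min_detectable_diameter(0.2, 1), 0.2)
  expect_error(resolution_mm_per_px(490, 0), "sensor_px_across")
})
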