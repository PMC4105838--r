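#' Relative deviation of a measurement from ground truth
#'
#' Absolute relative deviation in percent, `100 * |measured - truth| /
#' truth`; with `signed = TRUE` the sign of the deviation is kept
#' (positive = overestimate). Vectorized over pairs.
#'
#' @param measured measured values (mm).
#' @param truth ground-truth values (mm), strictly positive.
#' @param signed keep the sign instead of taking the absolute value.
#' @return Deviations in percent.
#' @export
relative_deviation <- function(measured, truth, signed = FALSE) {
  if (length(measured) != length(truth))
    stop_param("measured and truth lengths differ")
  if (any(!is.finite(truth)) || any(truth <= 0))
    stop_param("truth must be finite and > 0")
  dev <- 100 * (measured - truth) / truth
  if (signed) dev else abs(dev)
}

#' Repeatability from a complete image-by-user table
#'
#' Two-way random-effects variance components estimated by method-of-moments
#' ANOVA (expected mean squares) from a complete table of one measurement
#' per image and user. The repeatability is
#' `R2 = var_image / (var_image + var_error)`, where `var_image` is the
#' variance between images and `var_error` the image-by-user interaction
#' plus residual variance (inseparable without replication). Negative
#' moment estimates are truncated to zero; when nothing distinguishes the
#' images (`var_image = 0`) the repeatability is 0 by convention.
#'
#' @param values numeric matrix (rows = images, columns = users) or a data
#'   frame with columns `image`, `user`, `value`; the table must be
#'   complete, with at least 2 images and 2 users.
#' @return List of class `repeatability_result`: `var_image`, `var_error`,
#'   `R2`, and the mean squares `ms`.
#' @export
repeatability <- function(values) {
  if (is.data.frame(values)) {
    if (!all(c("image", "user", "value") %in% names(values)))
      stop_param("long-format input needs columns image, user, value")
    tab <- tapply(values$value, list(values$image, values$user), mean)
  } else if (is.matrix(values) && is.numeric(values)) {
    tab <- values
  } else stop_param("values must be a numeric matrix or a long data frame")
  if (anyNA(tab)) stop_param("incomplete table: every image-user cell is required")
  n_img <- nrow(tab); n_usr <- ncol(tab)
  if (n_img < 2L || n_usr < 2L) stop_param("need >= 2 images and >= 2 users")
  gm <- mean(tab)
  img_means <- rowMeans(tab)
  usr_means <- colMeans(tab)
  ss_img <- n_usr * sum((img_means - gm)^2)
  ss_usr <- n_img * sum((usr_means - gm)^2)
  resid <- tab - outer(img_means, rep(1, n_usr)) -
    outer(rep(1, n_img), usr_means) + gm
  ss_res <- sum(resid^2)
  ms_img <- ss_img / (n_img - 1L)
  ms_usr <- ss_usr / (n_usr - 1L)
  ms_res <- ss_res / ((n_img - 1L) * (n_usr - 1L))
  var_image <- max(0, (ms_img - ms_res) / n_usr)
  var_error <- ms_res
  r2 <- if (var_image == 0) 0 else var_image / (var_image + var_error)
  structure(list(var_image = var_image, var_error = var_error, R2 = r2,
                 ms = c(image = ms_img, user = ms_usr, residual = ms_res)),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability> R2 = %.3f (var_image %.4g, var_error %.4g)\n",
              x$R2, x$var_image, x$var_error))
  invisible(x)
}

#' Pairwise squared correlation between measurement backends
#'
#' Squared Pearson correlation of per-image values for every pair of
#' backends; the standard agreement statistic for comparing root-measurement
#' software on a common image set.
#'
#' @param lengths numeric matrix, rows = images (>= 3), columns = backends.
#' @return Symmetric r^2 matrix with unit diagonal.
#' @export
pairwise_r2 <- function(lengths) {
  lengths <- as.matrix(lengths)
  if (nrow(lengths) < 3L) stop_param("need >= 3 images")
  sds <- apply(lengths, 2L, sd)
  if (any(sds == 0))
    stop_param("backend '", colnames(lengths)[which(sds == 0)[1]] %||%
                 which(sds == 0)[1], "' has zero variance: r2 undefined")
  cor(lengths)^2
}

# vector-replay measurement backend: integrates the resampled generating
# centerlines, i.e. measures the vector description rather than the raster
replay_length <- function(system, step = 0.5) {
  sum(vapply(system$roots,
             function(r) max(resample_centerline(r, step = step)$s), numeric(1)))
}

#' Benchmark skeleton measurement against generated ground truth
#'
#' The artificial-root accuracy experiment: generates `n_systems` random
#' root systems, renders each noiselessly at high contrast, segments with
#' the adaptive threshold, measures total root length on the pruned
#' skeleton, and scores it against the known spline arc length. A second,
#' independent backend (vector replay: integrating the resampled generating
#' centerlines) measures the same images, giving a cross-backend r^2 on per
#' image totals.
#'
#' @param n_systems number of systems/images (>= 2).
#' @param seed integer seed; the run is fully deterministic given the seed.
#' @param config a [render_config()]; the default renders noiseless
#'   high-contrast images at 0.13 mm/px.
#' @param extent scene extent in mm passed to [generate_root_system()].
#' @param block_size,proportion adaptive-threshold parameters.
#' @param min_object_px speckle-removal size for [clean_mask()].
#' @param prune_px spur-pruning length for [measure_mask()].
#' @return List of class `root_benchmark`: `results` (per-image data frame
#'   with truth, skeleton and replay lengths plus signed percent
#'   deviations), `r2` (backend r^2 matrix), `max_deviation_pct`,
#'   `mean_deviation_pct`.
#' @examples
#' \donttest{
#' bm <- run_benchmark(n_systems = 3, seed = 7)
#' bm$max_deviation_pct
#' }
#' @export
run_benchmark <- function(n_systems = 10, seed = 42, config = render_config(),
                          extent = c(60, 80), block_size = 64,
                          proportion = 0.1, min_object_px = 20, prune_px = 5) {
  check_number(n_systems, "n_systems", positive = TRUE, integer = TRUE)
  if (n_systems < 2) stop_param("n_systems must be >= 2")
  params <- with_seed(seed, data.frame(
    sys_seed = sample.int(2^30, n_systems),
    n_axile = sample(2:4, n_systems, replace = TRUE),
    laterals_per_cm = runif(n_systems, 0.8, 2.5)))
  rows <- vector("list", n_systems)
  for (i in seq_len(n_systems)) {
    sys <- generate_root_system(n_axile = params$n_axile[i],
                                laterals_per_cm = params$laterals_per_cm[i],
                                extent = extent, seed = params$sys_seed[i])
    rr <- render(sys, config)
    mask <- clean_mask(adaptive_threshold(rr$image, block_size, proportion,
                                          "root_bright"),
                       min_object_px = min_object_px)
    rep <- measure_mask(mask, prune_px = prune_px)
    rows[[i]] <- data.frame(system = i,
                            truth_mm = sum(rr$truth$length_mm),
                            skeleton_mm = rep$total_length,
                            replay_mm = replay_length(sys))
  }
  res <- do.call(rbind, rows)
  res$dev_skeleton_pct <- relative_deviation(res$skeleton_mm, res$truth_mm, signed = TRUE)
  res$dev_replay_pct <- relative_deviation(res$replay_mm, res$truth_mm, signed = TRUE)
  r2 <- pairwise_r2(cbind(skeleton = res$skeleton_mm, replay = res$replay_mm))
  structure(list(results = res, r2 = r2,
                 max_deviation_pct = max(abs(res$dev_skeleton_pct)),
                 mean_deviation_pct = mean(abs(res$dev_skeleton_pct))),
            class = "root_benchmark")
}

#' @export
print.root_benchmark <- function(x, ...) {
  cat(sprintf("<root_benchmark> %d images\n", nrow(x$results)))
  cat(sprintf("  skeleton backend: max |deviation| %.2f%%, mean %.2f%%\n",
              x$max_deviation_pct, x$mean_deviation_pct))
  cat(sprintf("  replay backend:   max |deviation| %.3f%%\n",
              max(abs(x$results$dev_replay_pct))))
  cat(sprintf("  skeleton vs replay r2 = %.4f\n", x$r2["skeleton", "replay"]))
  invisible(x)
}
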