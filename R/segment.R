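#' Binary root masks
#'
#' A `binary_mask` is a logical H x W matrix (TRUE = root) carrying the pixel
#' size, produced by the thresholding routines and consumed by the
#' measurement module.
#'
#' @param mask logical matrix.
#' @param mm_per_px pixel size in mm.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(mask, mm_per_px) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop_param("mask must be a logical matrix")
  check_number(mm_per_px, "mm_per_px", positive = TRUE)
  structure(mask, mm_per_px = mm_per_px, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g mm/px, %d foreground px (%.2f%%)\n",
              nrow(x), ncol(x), mm_per_px(x), sum(x), 100 * mean(x)))
  invisible(x)
}

as_gray_matrix <- function(gray) {
  if (inherits(gray, "raster_image")) {
    if (is_rgb(gray)) stop_param("expected a grayscale image")
    list(px = unclass(gray), range = 2^bit_depth(gray) - 1, mm = mm_per_px(gray))
  } else if (is.matrix(gray) && is.numeric(gray)) {
    list(px = gray, range = 255, mm = attr(gray, "mm_per_px") %||% 1)
  } else stop_param("expected a grayscale raster_image or numeric matrix")
}

#' Global thresholding
#'
#' Classifies every pixel against a single tonal value. With
#' `polarity = "root_dark"` (dark roots on bright paper, the scanner
#' convention) pixels strictly below `t` are root and all others background;
#' with `"root_bright"` pixels strictly above `t` are root. Pixels equal to
#' `t` are always background.
#'
#' @param gray grayscale [raster_image] (or numeric matrix).
#' @param t threshold, tonal units within the image's range.
#' @param polarity `"root_bright"` or `"root_dark"`.
#' @return A [binary_mask].
#' @export
global_threshold <- function(gray, t, polarity = c("root_bright", "root_dark")) {
  g <- as_gray_matrix(gray)
  polarity <- match.arg(polarity)
  check_number(t, "t")
  if (t < 0 || t > g$range) stop_param("threshold outside [0, ", g$range, "]")
  m <- if (polarity == "root_dark") g$px < t else g$px > t
  binary_mask(m, g$mm)
}

#' Automatic threshold selection (Otsu criterion)
#'
#' Exhaustively scans all integer tonal values and returns the threshold
#' maximizing the between-class variance of the resulting two classes; the
#' returned value lies strictly between the minimum and maximum intensity.
#' Stands in for the unpublished automatic routine of commercial root
#' software.
#'
#' @param gray grayscale [raster_image] (or numeric matrix).
#' @return The selected threshold (tonal value).
#' @export
auto_threshold <- function(gray) {
  g <- as_gray_matrix(gray)
  v <- round(as.numeric(g$px))
  if (min(v) == max(v)) stop_param("cannot auto-threshold a constant image")
  h <- tabulate(v + 1L, nbins = g$range + 1L)
  n <- length(v)
  lev <- 0:g$range
  w0 <- cumsum(h) / n                    # weight of class {<= t}
  mu0 <- cumsum(h * lev) / n             # unnormalized class-0 mean
  mu_t <- mu0[length(mu0)]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  # split after level k -> threshold k + 0.5 lies strictly between the modes
  lev[which.max(between)] + 0.5
}

#' Adaptive (block-mean) thresholding
#'
#' The image is broken up into non-overlapping square blocks of
#' `block_size` px (edge blocks smaller); within each block the mean pixel
#' intensity is computed, and a pixel is foreground when its deviation from
#' the block mean, in the polarity direction, exceeds `proportion` of the
#' tonal range. With `smooth = TRUE` the tiled block mean is replaced by a
#' per-pixel moving-window mean of the same size, a variant that avoids
#' block-boundary artefacts.
#'
#' @param gray grayscale [raster_image] (or numeric matrix).
#' @param block_size block edge length in px (>= 3).
#' @param proportion fraction of the tonal range a pixel must deviate from
#'   the local mean to count as root, in (0, 1).
#' @param polarity `"root_bright"` or `"root_dark"`.
#' @param smooth use a per-pixel moving mean instead of tiled blocks.
#' @return A [binary_mask].
#' @export
adaptive_threshold <- function(gray, block_size = 64, proportion = 0.1,
                               polarity = c("root_bright", "root_dark"),
                               smooth = FALSE) {
  g <- as_gray_matrix(gray)
  polarity <- match.arg(polarity)
  check_number(block_size, "block_size", positive = TRUE, integer = TRUE)
  if (block_size < 3) stop_param("block_size must be >= 3")
  if (block_size > max(dim(g$px))) stop_param("block_size exceeds both image dimensions")
  check_number(proportion, "proportion")
  if (proportion <= 0 || proportion >= 1) stop_param("proportion must be in (0, 1)")
  if (smooth) {
    local_mean <- box_mean(g$px, block_size)
  } else {
    ri <- ceiling(seq_len(nrow(g$px)) / block_size)
    ci <- ceiling(seq_len(ncol(g$px)) / block_size)
    grp_r <- ri[row(g$px)]
    grp_c <- ci[col(g$px)]
    grp <- (grp_r - 1L) * max(ci) + grp_c
    means <- rowsum(as.vector(g$px), as.vector(grp)) /
      as.vector(table(as.vector(grp)))
    local_mean <- matrix(means[as.character(as.vector(grp)), 1L],
                         nrow(g$px), ncol(g$px))
  }
  dev <- if (polarity == "root_bright") g$px - local_mean else local_mean - g$px
  binary_mask(dev > proportion * g$range, g$mm)
}

#' Double-adaptive thresholding
#'
#' Examines the behaviour of the local mean as a function of neighbourhood
#' size: a pixel is foreground when its polarity-signed deviation from the
#' neighbourhood mean exceeds `min_change` of the tonal range for at least
#' one size, and the means move monotonically away from the pixel value as
#' the neighbourhood grows. The monotonicity requirement suppresses
#' high-frequency paper-texture noise, for which the local mean fluctuates
#' instead of drifting.
#'
#' @param gray grayscale [raster_image] (or numeric matrix).
#' @param neighborhood_sizes strictly increasing vector (>= 2 sizes) of
#'   square window edge lengths in px.
#' @param min_change minimum deviation as a fraction of the tonal range.
#' @param polarity `"root_bright"` or `"root_dark"`.
#' @return A [binary_mask].
#' @export
double_adaptive_threshold <- function(gray, neighborhood_sizes = c(5, 15, 31),
                                      min_change = 0.1,
                                      polarity = c("root_bright", "root_dark")) {
  g <- as_gray_matrix(gray)
  polarity <- match.arg(polarity)
  if (length(neighborhood_sizes) < 2L || any(diff(neighborhood_sizes) <= 0))
    stop_param("neighborhood_sizes must be >= 2 strictly increasing sizes")
  check_number(min_change, "min_change")
  sgn <- if (polarity == "root_bright") 1 else -1
  devs <- lapply(neighborhood_sizes,
                 function(s) sgn * (g$px - box_mean(g$px, s)))
  big_enough <- Reduce(`|`, lapply(devs, function(d) d > min_change * g$range))
  mono <- Reduce(`&`, mapply(function(a, b) b >= a - 1e-6,
                             devs[-length(devs)], devs[-1L], SIMPLIFY = FALSE))
  binary_mask(big_enough & mono, g$mm)
}

#' Remove small components and fill holes in a mask
#'
#' Deletes 8-connected foreground components smaller than `min_object_px`
#' (speckle noise from paper texture) and optionally fills enclosed
#' background holes.
#'
#' @param mask a [binary_mask].
#' @param min_object_px minimum component size in px to keep.
#' @param fill_holes fill enclosed background holes.
#' @return The cleaned [binary_mask].
#' @export
clean_mask <- function(mask, min_object_px = 20, fill_holes = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  check_number(min_object_px, "min_object_px")
  if (min_object_px < 0) stop_param("min_object_px must be >= 0")
  m <- unclass(mask) * 1
  if (min_object_px > 0 && any(m > 0)) {
    lab <- label8_cpp(matrix(as.logical(mask), nrow(mask), ncol(mask)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, nrow(mask), ncol(mask)) * 1
  }
  if (fill_holes && any(m > 0)) m <- EBImage::fillHull(m)
  binary_mask(matrix(as.numeric(m) > 0, nrow(mask), ncol(mask)), mm_per_px(mask))
}
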