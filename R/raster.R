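#' Raster image with physical scale
#'
#' Lightweight container for 8-bit root images: a numeric `H x W` matrix
#' (grayscale) or `H x W x 3` array (RGB) with the physical pixel size
#' attached. Row 1 is the top of the image and the origin of the millimetre
#' coordinate system is the top-left corner, so image row order matches the
#' y-axis of vectorized root systems.
#'
#' @param pixels numeric matrix (grayscale) or `H x W x 3` array (RGB),
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param mm_per_px physical size of one pixel in mm.
#' @param bit_depth tonal bit depth; 8 for the standard camera workflow.
#' @return A `raster_image` object.
#' @examples
#' img <- raster_image(matrix(40, 20, 30), mm_per_px = 0.13)
#' dim(img)
#' @export
raster_image <- function(pixels, mm_per_px, bit_depth = 8L) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop_param("pixels must be a numeric matrix or H x W x 3 array")
  if (length(dim(pixels)) == 3L && dim(pixels)[3L] != 3L)
    stop_param("multi-channel images must have exactly 3 channels")
  check_number(mm_per_px, "mm_per_px", positive = TRUE)
  check_number(bit_depth, "bit_depth", positive = TRUE, integer = TRUE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop_param("intensities outside [0, ", 2^bit_depth - 1, "]")
  structure(pixels, mm_per_px = mm_per_px, bit_depth = as.integer(bit_depth),
            class = c("raster_image", class(pixels)))
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image> %d x %d px, %s, %d-bit, %.4g mm/px\n",
              d[1], d[2], if (length(d) == 3L) "RGB" else "grayscale",
              bit_depth(x), mm_per_px(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
plot.raster_image <- function(x, ...) {
  m <- if (length(dim(x)) == 3L) apply(unclass(x), c(1, 2), mean) else unclass(x)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = grDevices::gray.colors(256, 0, 1),
                  asp = nrow(m) / ncol(m), axes = FALSE, ...)
  invisible(x)
}

#' Physical and tonal metadata of raster containers
#'
#' @param x a `raster_image`, `binary_mask` or `skeleton` object.
#' @return `mm_per_px()` the pixel size in mm; `bit_depth()` the tonal depth.
#' @export
mm_per_px <- function(x) attr(x, "mm_per_px")

#' @rdname mm_per_px
#' @export
bit_depth <- function(x) attr(x, "bit_depth") %||% 8L

is_rgb <- function(x) length(dim(x)) == 3L

# rebuild an image carrying over metadata from a template
rebuild_image <- function(pixels, template, clip = TRUE) {
  if (clip) {
    lim <- 2^bit_depth(template) - 1
    pixels[pixels < 0] <- 0
    pixels[pixels > lim] <- lim
  }
  raster_image(pixels, mm_per_px(template), bit_depth(template))
}

#' Read and write root images
#'
#' PNG (and TIFF, when the tiff package is available) input/output for
#' [raster_image] objects. The pixel size is stored next to the image in a
#' plain-text sidecar file `<path>.meta` (DCF format, field `mm_per_px`), and
#' read back from there; `mm_per_px` passed explicitly overrides the sidecar.
#'
#' @param path image file path (`.png`, `.tif`/`.tiff`).
#' @param mm_per_px pixel size in mm; if `NULL`, taken from the sidecar file.
#' @param image a [raster_image].
#' @return `read_image()` a [raster_image]; `write_image()` `path`, invisibly.
#' @export
read_image <- function(path, mm_per_px = NULL) {
  if (!file.exists(path)) stop_param("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_param("the tiff package is required to read TIFF files")
      tiff::readTIFF(path)
    },
    stop_param("unsupported image format: .", ext))
  if (length(dim(px)) == 3L && dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE] # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3L] == 1L) px <- px[, , 1L]
  if (is.null(mm_per_px)) {
    meta <- paste0(path, ".meta")
    if (file.exists(meta)) {
      dcf <- read.dcf(meta)
      if ("mm_per_px" %in% colnames(dcf)) mm_per_px <- as.numeric(dcf[1, "mm_per_px"])
    }
  }
  if (is.null(mm_per_px)) stop_param("mm_per_px not given and no sidecar metadata for ", path)
  raster_image(round(px * 255), mm_per_px, 8L)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- unclass(image) / (2^bit_depth(image) - 1)
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_param("the tiff package is required to write TIFF files")
      tiff::writeTIFF(norm, path)
    },
    stop_param("unsupported image format: .", ext))
  write.dcf(data.frame(mm_per_px = mm_per_px(image)), paste0(path, ".meta"))
  invisible(path)
}
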