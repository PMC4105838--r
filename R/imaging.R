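#' Minimum-tonal fusion of a left/right illuminated image pair
#'
#' Combines two photographs of the same scene taken with flash illumination
#' from the left and from the right by keeping, per pixel and channel, the
#' minimum tonal value. Specular reflections (droplets, folds in the cover
#' foil) appear at illumination-dependent positions and are suppressed, while
#' root shadows cast to either side are retained, increasing local contrast.
#'
#' @param left,right [raster_image]s of identical shape, bit depth and scale.
#' @return The fused [raster_image].
#' @export
fuse_min <- function(left, right) {
  stopifnot(inherits(left, "raster_image"), inherits(right, "raster_image"))
  if (!identical(dim(left), dim(right)))
    stop_param("left and right images differ in shape")
  if (bit_depth(left) != bit_depth(right) || mm_per_px(left) != mm_per_px(right))
    stop_param("left and right images differ in bit depth or scale")
  rebuild_image(pmin(unclass(left), unclass(right)), left, clip = FALSE)
}

#' Estimate the smooth illumination field of a grayscale image
#'
#' Large-window median filtering (which removes thin bright roots) followed
#' by Gaussian smoothing yields a strictly positive low-pass estimate of the
#' background brightness, the flat-field model used by
#' [correct_illumination()].
#'
#' @param image grayscale [raster_image].
#' @param kernel_scale window size in px; must be at least 10 px and should be
#'   at least 5 times the largest expected root diameter in px so that roots
#'   are rejected by the median.
#' @return A `flatfield_model` list with elements `background` (matrix),
#'   `method` and `kernel_scale`.
#' @export
estimate_flatfield <- function(image, kernel_scale = 75) {
  stopifnot(inherits(image, "raster_image"))
  if (is_rgb(image)) stop_param("estimate_flatfield expects a grayscale image")
  check_number(kernel_scale, "kernel_scale", positive = TRUE)
  if (kernel_scale < 10) stop_param("kernel_scale must be >= 10 px")
  if (kernel_scale > min(dim(image)[1:2]))
    stop_param("kernel_scale exceeds the image size")
  lim <- 2^bit_depth(image) - 1
  med <- EBImage::medianFilter(unclass(image) / lim, max(1L, floor(kernel_scale / 2))) * lim
  bg <- EBImage::gblur(med, sigma = kernel_scale / 4, boundary = "replicate")
  bg <- pmax(as.numeric(bg), 1e-3)
  structure(list(background = matrix(bg, nrow(image), ncol(image)),
                 method = "median+gaussian", kernel_scale = kernel_scale),
            class = "flatfield_model")
}

#' @export
print.flatfield_model <- function(x, ...) {
  cat(sprintf("<flatfield_model> %d x %d px, %s, kernel %g px, range [%.1f, %.1f]\n",
              nrow(x$background), ncol(x$background), x$method, x$kernel_scale,
              min(x$background), max(x$background)))
  invisible(x)
}

#' Divisive flat-field illumination correction
#'
#' Divides the image by the flat-field background estimate and rescales so
#' the output mean equals the input mean, clipping to the tonal range. The
#' divisive model matches the multiplicative vignetting of flash lighting;
#' local root/background contrast ratios are preserved. RGB images are
#' corrected channel-wise with the same model.
#'
#' @param image a [raster_image].
#' @param model a `flatfield_model` from [estimate_flatfield()] with the same
#'   spatial shape.
#' @return The corrected [raster_image].
#' @export
correct_illumination <- function(image, model) {
  stopifnot(inherits(image, "raster_image"), inherits(model, "flatfield_model"))
  if (!all(dim(image)[1:2] == dim(model$background)))
    stop_param("image and flat-field model differ in shape")
  if (any(model$background <= 0)) stop_param("flat-field model must be strictly positive")
  fix_one <- function(ch) {
    out <- ch / model$background
    out * mean(ch) / mean(out)
  }
  px <- unclass(image)
  out <- if (is_rgb(image)) {
    for (k in 1:3) px[, , k] <- fix_one(px[, , k])
    px
  } else fix_one(px)
  rebuild_image(out, image)
}

#' Convert an RGB image to grayscale by channel selection
#'
#' Returns the selected colour channel unchanged (or the channel mean). The
#' red channel gives the strongest root/background contrast on blue and grey
#' germination papers, whose reflectance between 560 and 720 nm is about half
#' the root's.
#'
#' @param image RGB [raster_image] (grayscale input is passed through only
#'   with `channel = "mean"`).
#' @param channel one of `"red"`, `"green"`, `"blue"`, `"mean"`.
#' @return Grayscale [raster_image].
#' @export
to_gray <- function(image, channel = c("red", "green", "blue", "mean")) {
  stopifnot(inherits(image, "raster_image"))
  channel <- match.arg(channel)
  if (!is_rgb(image)) {
    if (channel != "mean")
      stop_param("single-channel image has no '", channel, "' channel")
    return(image)
  }
  px <- unclass(image)
  out <- switch(channel,
                red = px[, , 1L], green = px[, , 2L], blue = px[, , 3L],
                mean = (px[, , 1L] + px[, , 2L] + px[, , 3L]) / 3)
  rebuild_image(out, image, clip = FALSE)
}

#' Two-flash preprocessing workflow
#'
#' The full preprocessing chain for a left/right illuminated image pair:
#' each image is flat-field corrected ([estimate_flatfield()] on its channel
#' mean, then [correct_illumination()]), the corrected pair is combined by
#' minimum tonal value ([fuse_min()]), and the result is converted to
#' grayscale by channel extraction ([to_gray()], red by default).
#' Intermediate arithmetic is kept in floating point; quantization to the
#' 8-bit range happens once per stage output.
#'
#' @param left,right matched RGB (or grayscale) [raster_image]s.
#' @param channel colour channel for the grayscale conversion.
#' @param kernel_scale flat-field window in px, see [estimate_flatfield()].
#' @return Grayscale [raster_image].
#' @export
preprocess <- function(left, right, channel = "red", kernel_scale = 75) {
  fix <- function(img) {
    lum <- if (is_rgb(img)) to_gray(img, "mean") else img
    correct_illumination(img, estimate_flatfield(lum, kernel_scale))
  }
  fused <- fuse_min(fix(left), fix(right))
  to_gray(fused, if (is_rgb(fused)) channel else "mean")
}
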