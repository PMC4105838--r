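#' Rendering configuration for artificial root images
#'
#' Parameters controlling how a vectorized [root_system] is rasterized into an
#' artificial root image. Roots are drawn brighter than the background (the
#' red-channel appearance of roots on blue germination paper); the
#' cross-section of a root of local diameter d is a Gaussian whose full width
#' at half maximum equals d, i.e. `sigma = d / (2 * sqrt(2 * log(2)))`.
#'
#' @param mm_per_px pixel size in mm (default 0.13, the full-slide camera
#'   resolution of the standard setup).
#' @param foreground_amplitude peak intensity added by a root centerline, in
#'   tonal units.
#' @param background_level paper background intensity, tonal units.
#' @param noise_sd standard deviation of additive Gaussian sensor noise,
#'   tonal units; 0 for noiseless renders.
#' @param ragged_edges if `TRUE`, the local diameter is jittered along the
#'   centerline (Gaussian, sd = 20% of the local diameter) to emulate the
#'   ragged root/background boundary caused by root hairs and reflections.
#' @param bit_depth tonal bit depth of the output image.
#' @return A `render_config` list.
#' @export
render_config <- function(mm_per_px = 0.13, foreground_amplitude = 180,
                          background_level = 40, noise_sd = 0,
                          ragged_edges = FALSE, bit_depth = 8L) {
  check_number(mm_per_px, "mm_per_px", positive = TRUE)
  check_number(foreground_amplitude, "foreground_amplitude")
  check_number(background_level, "background_level")
  check_number(noise_sd, "noise_sd")
  lim <- 2^bit_depth - 1
  if (background_level < 0 || background_level > lim)
    stop_param("background_level outside [0, ", lim, "]")
  if (foreground_amplitude < 0 || foreground_amplitude > lim)
    stop_param("foreground_amplitude outside [0, ", lim, "]")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  structure(list(mm_per_px = mm_per_px,
                 foreground_amplitude = foreground_amplitude,
                 background_level = background_level, noise_sd = noise_sd,
                 ragged_edges = isTRUE(ragged_edges),
                 bit_depth = as.integer(bit_depth)),
            class = "render_config")
}

#' Render a root system to an artificial root image with known ground truth
#'
#' Rasterizes every root of `system` by placing Gaussian cross-sections along
#' its densely resampled spline centerline: each pixel receives
#' `background_level + foreground_amplitude * exp(-r^2 / (2 sigma^2))`, where
#' `r` is the distance to the nearest centerline point and `sigma` matches the
#' local diameter by full width at half maximum. Overlapping roots combine by
#' maximum (an opaque root lying over another). The returned ground truth
#' holds the spline arc length of every root, the quantity that downstream
#' measurement is scored against.
#'
#' Roots thinner than one pixel at the configured scale are rendered anyway
#' but flagged `sub_resolution` in the ground truth (with a warning): below
#' about three pixels they cannot be measured reliably.
#'
#' @param system a [root_system].
#' @param config a [render_config()].
#' @param seed seed for the noise and ragged-edge perturbations; defaults to
#'   the system's own seed so identical seeds give identical images.
#' @return List of class `rendered_roots` with elements `image` (a grayscale
#'   [raster_image]), `truth` (per-root data frame: `id`, `order`,
#'   `length_mm`, `length_px`, `mean_diameter_mm`, `sub_resolution`) and
#'   `config`.
#' @examples
#' rs <- generate_root_system(n_axile = 1, laterals_per_cm = 0, seed = 1)
#' rr <- render(rs, render_config())
#' rr$truth$length_mm
#' @export
render <- function(system, config = render_config(), seed = NULL) {
  stopifnot(inherits(system, "root_system"), inherits(config, "render_config"))
  if (!length(system$roots)) stop_param("system has no roots")
  s <- config$mm_per_px
  W <- max(1L, round(system$extent[1] / s))
  H <- max(1L, round(system$extent[2] / s))
  fwhm_k <- 2 * sqrt(2 * log(2))
  seed <- seed %||% system$seed %||% 0L
  with_seed(seed, {
    canvas <- matrix(0, H, W)
    truth <- vector("list", length(system$roots))
    for (i in seq_along(system$roots)) {
      r <- system$roots[[i]]
      dense <- resample_centerline(r, step = 0.35 * s)
      d <- dense$diameter
      if (config$ragged_edges) {
        # per-boundary-pixel jitter: one draw per pixel of arc length,
        # interpolated onto the dense samples so bumps survive compositing
        knots <- seq(0, max(dense$s), by = s)
        if (length(knots) < 2L) knots <- c(0, max(dense$s))
        z <- approx(knots, rnorm(length(knots)), xout = dense$s, rule = 2)$y
        d <- pmax(0.05 * dense$diameter, dense$diameter * (1 + 0.2 * z))
      }
      sigma_px <- (d / fwhm_k) / s
      canvas <- paint_gaussian_max(canvas, dense$y / s - 0.5, dense$x / s - 0.5,
                                   sigma_px, config$foreground_amplitude)
      truth[[i]] <- data.frame(id = r$id, order = r$order,
                               length_mm = max(dense$s),
                               length_px = max(dense$s) / s,
                               mean_diameter_mm = mean(dense$diameter),
                               sub_resolution = min(dense$diameter) < s)
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    if (any(truth$sub_resolution))
      warning(sum(truth$sub_resolution), " root(s) thinner than one pixel at ",
              s, " mm/px", call. = FALSE)
    img <- config$background_level + canvas
    if (config$noise_sd > 0) img <- img + rnorm(length(img), 0, config$noise_sd)
    lim <- 2^config$bit_depth - 1
    img <- round(pmin(pmax(img, 0), lim))
    structure(list(image = raster_image(img, s, config$bit_depth),
                   truth = truth, config = config),
              class = "rendered_roots")
  })
}

#' @export
print.rendered_roots <- function(x, ...) {
  cat(sprintf("<rendered_roots> %d x %d px at %.3g mm/px, %d roots, total %.1f mm\n",
              nrow(x$image), ncol(x$image), mm_per_px(x$image),
              nrow(x$truth), sum(x$truth$length_mm)))
  if (any(x$truth$sub_resolution))
    cat("  note:", sum(x$truth$sub_resolution), "sub-resolution root(s)\n")
  invisible(x)
}
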