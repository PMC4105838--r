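#' Reflectance spectra with exposure metadata
#'
#' A `spectral_curve` holds sensor intensities on a strictly increasing
#' wavelength grid (nm) together with the exposure time the measurement was
#' taken at. Raw hyperspectral intensities are comparable only after
#' exposure correction ([correct_exposure()]) and normalization against a
#' white reference ([normalize_to_reference()]).
#'
#' @param wavelength_nm strictly increasing wavelength grid, nm.
#' @param intensity non-negative intensities, arbitrary sensor units (or
#'   dimensionless reflectance once normalized).
#' @param exposure_s exposure time in seconds.
#' @return A `spectral_curve` data frame.
#' @export
spectral_curve <- function(wavelength_nm, intensity, exposure_s) {
  if (length(wavelength_nm) != length(intensity))
    stop_param("wavelength_nm and intensity lengths differ")
  if (any(diff(wavelength_nm) <= 0))
    stop_param("wavelengths must be strictly increasing")
  if (any(intensity < 0)) stop_param("intensities must be >= 0")
  check_number(exposure_s, "exposure_s", positive = TRUE)
  structure(data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
            exposure_s = exposure_s,
            class = c("spectral_curve", "data.frame"))
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %d points, %g-%g nm, exposure %g s\n",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
              attr(x, "exposure_s")))
  invisible(x)
}

#' @export
plot.spectral_curve <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$intensity, type = "l",
                 xlab = "wavelength (nm)", ylab = "intensity", ...)
  invisible(x)
}

#' Exposure time of a spectral curve
#' @param x a `spectral_curve`.
#' @return Exposure time in seconds.
#' @export
exposure_s <- function(x) attr(x, "exposure_s")

#' Correct a spectrum for its exposure time
#'
#' Scales every intensity by `reference_exposure / exposure_s(sample)` so
#' that spectra recorded at different exposure times become comparable to
#' the white-reference measurement.
#'
#' @param sample a `spectral_curve`.
#' @param reference_exposure exposure time of the reference measurement, s.
#' @return The corrected `spectral_curve`, with its exposure set to
#'   `reference_exposure`.
#' @export
correct_exposure <- function(sample, reference_exposure) {
  stopifnot(inherits(sample, "spectral_curve"))
  check_number(reference_exposure, "reference_exposure", positive = TRUE)
  spectral_curve(sample$wavelength_nm,
                 sample$intensity * reference_exposure / exposure_s(sample),
                 reference_exposure)
}

#' Normalize a spectrum against a white reference
#'
#' Exposure-corrects the sample to the reference's exposure time and divides
#' pointwise by the reference intensities (a diffuse white standard), giving
#' dimensionless relative reflectance.
#'
#' @param sample,reference `spectral_curve`s on a common wavelength grid;
#'   reference intensities must be strictly positive.
#' @return A dimensionless `spectral_curve` of relative reflectance.
#' @export
normalize_to_reference <- function(sample, reference) {
  stopifnot(inherits(sample, "spectral_curve"), inherits(reference, "spectral_curve"))
  if (!isTRUE(all.equal(sample$wavelength_nm, reference$wavelength_nm)))
    stop_param("sample and reference are on different wavelength grids")
  if (any(reference$intensity <= 0)) {
    bad <- reference$wavelength_nm[which(reference$intensity <= 0)[1]]
    stop_param("reference intensity is zero at ", bad, " nm")
  }
  corr <- correct_exposure(sample, exposure_s(reference))
  spectral_curve(sample$wavelength_nm, corr$intensity / reference$intensity,
                 exposure_s(reference))
}

#' Named wavelength bands of the camera channels
#'
#' Default band edges: blue 450-490, green 520-560, red 620-720 and
#' near-infrared 790-1000 nm. The visible edges follow the usual camera
#' channel ranges; the NIR interval is the standard 790-1000 nm window.
#'
#' @param blue,green,red,nir `c(lower, upper)` wavelength intervals in nm.
#' @return Named list of bands, class `band_set`.
#' @export
band_set <- function(blue = c(450, 490), green = c(520, 560),
                     red = c(620, 720), nir = c(790, 1000)) {
  bands <- list(blue = blue, green = green, red = red, nir = nir)
  for (b in names(bands))
    if (length(bands[[b]]) != 2L || diff(bands[[b]]) <= 0)
      stop_param("band '", b, "' must be c(lower, upper) nm")
  structure(bands, class = "band_set")
}

band_mean <- function(curve, band) {
  in_band <- curve$wavelength_nm >= band[1] & curve$wavelength_nm <= band[2]
  if (!any(in_band)) stop_param("band [", band[1], ", ", band[2],
                                "] nm does not intersect the wavelength grid")
  mean(curve$intensity[in_band])
}

#' Root/background contrast within a wavelength band
#'
#' Ratio of the band-mean reflectance of the root to that of the paper
#' background. A ratio far from 1 in either direction means good
#' segmentation contrast; blue and grey germination papers reflect about
#' half as much as the root between 560 and 720 nm (ratio 2), while white
#' paper reflects about twice as much (ratio 0.5).
#'
#' @param root,paper normalized `spectral_curve`s on a common grid.
#' @param band `c(lower, upper)` interval in nm.
#' @return The contrast ratio (root mean / paper mean).
#' @export
band_contrast <- function(root, paper, band) {
  stopifnot(inherits(root, "spectral_curve"), inherits(paper, "spectral_curve"))
  if (!isTRUE(all.equal(root$wavelength_nm, paper$wavelength_nm)))
    stop_param("root and paper are on different wavelength grids")
  band_mean(root, band) / band_mean(paper, band)
}

#' Recommend the camera channel for root/background segmentation
#'
#' Computes the band contrast of the root against every paper and selects
#' the band whose worst-case (over papers) absolute log-contrast is largest:
#' a channel is only useful if it separates root from background on every
#' paper in a batch. Ties are broken toward the longer wavelength.
#'
#' @param root normalized root `spectral_curve`.
#' @param papers list of normalized paper `spectral_curve`s (>= 1).
#' @param bands a [band_set()].
#' @return List of class `channel_recommendation`: `channel` (band name),
#'   `contrast` (papers x bands ratio matrix) and `score` (per-band
#'   worst-case |log contrast|).
#' @export
recommend_channel <- function(root, papers, bands = band_set()) {
  if (inherits(papers, "spectral_curve")) papers <- list(papers)
  if (!length(papers)) stop_param("at least one paper curve is required")
  if (is.null(names(papers)))
    names(papers) <- paste0("paper", seq_along(papers))
  contrast <- sapply(names(bands), function(b)
    vapply(papers, function(p) band_contrast(root, p, bands[[b]]), numeric(1)))
  contrast <- matrix(contrast, nrow = length(papers), ncol = length(bands),
                     dimnames = list(names(papers), names(bands)))
  score <- apply(abs(log(contrast)), 2L, min)
  centers <- vapply(bands, mean, numeric(1))
  best <- which(score >= max(score) - 1e-9)
  channel <- names(bands)[best[which.max(centers[best])]]
  structure(list(channel = channel, contrast = contrast, score = score),
            class = "channel_recommendation")
}

#' @export
print.channel_recommendation <- function(x, ...) {
  cat("<channel_recommendation> best band:", x$channel, "\n")
  cat("  worst-case |log contrast| per band:\n")
  print(round(x$score, 3))
  cat("  contrast (root/paper) per paper and band:\n")
  print(round(x$contrast, 3))
  invisible(x)
}

#' Read and write spectra as CSV
#'
#' Plain-text exchange format: a first comment line `# exposure_s: <t>`
#' followed by a CSV table with columns `wavelength_nm` and `intensity`.
#'
#' @param path CSV file path.
#' @param curve a `spectral_curve`.
#' @return `read_spectra_csv()` a `spectral_curve`; `write_spectra_csv()`
#'   `path`, invisibly.
#' @export
read_spectra_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*exposure_s:", first))
    stop_param("missing '# exposure_s:' header line in ", path)
  expo <- as.numeric(sub("^#\\s*exposure_s:\\s*", "", first))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop_param("expected columns wavelength_nm, intensity in ", path)
  spectral_curve(df$wavelength_nm, df$intensity, expo)
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(curve, path) {
  stopifnot(inherits(curve, "spectral_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exposure_s: %g", exposure_s(curve)), con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

# smooth step from `lo` to `hi` centred at x0 with half-width w (logistic)
smoothstep <- function(x, x0, w, lo, hi) lo + (hi - lo) / (1 + exp(-(x - x0) / w))

#' Fixture reflectance spectra of a root and five germination papers
#'
#' Deterministic synthetic curves (2-nm grid, 400-1000 nm) encoding the
#' qualitative reflectance relations measured for maize roots and
#' germination papers: the strongly coloured papers (steel blue, Whatman
#' blue, Sebio grey) reflect strongly in blue, drop to half the root's
#' reflectance between 560 and 720 nm and rise above it in the
#' near-infrared; light blue paper reflects more than the root throughout
#' with blue/NIR maxima; white paper reflects about twice the root
#' everywhere. Raw intensities are built as reflectance times a common lamp
#' curve, scaled by each measurement's exposure time (white standard 0.21 s;
#' steel blue, Whatman blue and Sebio grey 0.4 s; light blue 0.3 s; white
#' 0.25 s), so the exposure-correction/normalization chain recovers the
#' encoded reflectances. Seeded multiplicative noise (sd 0.2%) keeps the
#' curves from being exactly analytic.
#'
#' @param seed integer seed for the low-amplitude noise.
#' @return List with `root` (a `spectral_curve`), `papers` (named list:
#'   `steel_blue`, `whatman_blue`, `light_blue`, `white`, `sebio_grey`) and
#'   `spectralon` (the white-reference curve).
#' @export
make_fixture_spectra <- function(seed = 1) {
  wl <- seq(400, 1000, by = 2)
  lamp <- 500 + 2000 * exp(-((wl - 700) / 350)^2)
  t_ref <- 0.21
  root_refl <- 0.42 + 0.03 * sin((wl - 400) / 600 * pi)
  # ratio-to-root shapes; mid-band plateau [560, 720] held at exactly 0.5
  blue_like <- function(blue_ratio, nir_ratio) {
    smoothstep(wl, 540, 5, blue_ratio, 0.5) * (wl < 640) +
      (wl >= 640) * smoothstep(wl, 755, 8, 0.5, nir_ratio)
  }
  shapes <- list(
    steel_blue   = blue_like(1.30, 1.50),
    whatman_blue = blue_like(0.90, 1.40),
    light_blue   = 1.25 + 0.35 * exp(-((wl - 460) / 60)^2) +
                   0.35 * smoothstep(wl, 800, 40, 0, 1),
    white        = rep(2.0, length(wl)),
    sebio_grey   = blue_like(0.80, 1.50))
  expos <- c(steel_blue = 0.4, whatman_blue = 0.4, light_blue = 0.3,
             white = 0.25, sebio_grey = 0.4)
  with_seed(seed, {
    noisy <- function(x) x * (1 + rnorm(length(x), 0, 0.002))
    root_raw <- noisy(root_refl * lamp) * 0.35 / t_ref
    papers <- lapply(names(shapes), function(nm)
      spectral_curve(wl, noisy(shapes[[nm]] * root_refl * lamp) * expos[[nm]] / t_ref,
                     expos[[nm]]))
    names(papers) <- names(shapes)
    list(root = spectral_curve(wl, root_raw, 0.35),
         papers = papers,
         spectralon = spectral_curve(wl, lamp, t_ref))
  })
}
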