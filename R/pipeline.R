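#' Batch image-to-measurement pipeline
#'
#' Runs the full workflow for every left/right image pair in a directory:
#' preprocessing ([preprocess()]: per-image flat-field correction, minimum
#' tonal fusion, channel extraction), segmentation, mask cleaning and
#' skeleton measurement ([measure_mask()]). Pairs follow the naming
#' convention `<id>_L.<ext>` / `<id>_R.<ext>` (PNG or TIFF); with
#' `paired = FALSE` every image is processed alone and fusion is skipped.
#' One CSV row is written per image id; masks are saved as 0/255 grayscale
#' PNGs next to the report. Unreadable images are reported and skipped; the
#' batch continues and the failure count is attached to the result.
#'
#' @param input directory containing the images.
#' @param output output directory (created if missing) receiving
#'   `report.csv`, per-image `<id>_mask.png` files and `pipeline.log`.
#' @param channel colour channel for grayscale conversion.
#' @param method segmentation method: `"adaptive"`, `"double"`, `"global"`
#'   or `"auto"` (Otsu-selected global threshold).
#' @param polarity `"root_bright"` or `"root_dark"`.
#' @param global_t threshold for `method = "global"`.
#' @param block_size,proportion adaptive-threshold parameters.
#' @param neighborhood_sizes,min_change double-adaptive parameters.
#' @param mm_per_px pixel size in mm (overridden by sidecar metadata if
#'   present).
#' @param class_edges diameter class boundaries in mm.
#' @param prune_px spur-pruning length in px.
#' @param min_object_px speckle-removal size in px.
#' @param kernel_scale flat-field window in px.
#' @param paired expect `_L`/`_R` pairs (the two-flash convention).
#' @return Invisibly, the report data frame (one row per image id) with
#'   attributes `failures` (character vector of failed ids) and `paths`.
#' @export
run_pipeline <- function(input, output, channel = "red",
                         method = c("adaptive", "double", "global", "auto"),
                         polarity = "root_bright", global_t = 128,
                         block_size = 64, proportion = 0.1,
                         neighborhood_sizes = c(5, 15, 31), min_change = 0.1,
                         mm_per_px = 0.13, class_edges = 0.5, prune_px = 5,
                         min_object_px = 20, kernel_scale = 75,
                         paired = TRUE) {
  method <- match.arg(method)
  if (!dir.exists(input)) stop_param("input directory does not exist: ", input)
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("rootraster %s | method=%s channel=%s mm_per_px=%g",
       as.character(utils::packageVersion("rootraster")), method, channel, mm_per_px)

  files <- list.files(input, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  if (!length(files)) {
    warning("no images found in ", input, call. = FALSE)
    logf("no images found")
    rep <- empty_report()
    utils::write.csv(rep, file.path(output, "report.csv"), row.names = FALSE)
    return(invisible(structure(rep, failures = character(),
                               paths = list(report = file.path(output, "report.csv")))))
  }
  if (paired) {
    base <- sub("_[LR]\\.[^.]+$", "", files)
    side <- ifelse(grepl("_L\\.[^.]+$", files), "L",
                   ifelse(grepl("_R\\.[^.]+$", files), "R", NA))
    orphans <- files[is.na(side)]
    ids <- unique(base[!is.na(side)])
    for (id in ids) {
      have <- side[base == id]
      if (!all(c("L", "R") %in% have))
        orphans <- c(orphans, files[base == id])
    }
    if (length(orphans))
      stop_param("unpaired image files: ", paste(orphans, collapse = ", "))
  } else {
    ids <- tools::file_path_sans_ext(files)
  }

  rows <- list(); failures <- character()
  for (id in ids) {
    res <- tryCatch({
      gray <- if (paired) {
        lf <- file.path(input, files[base == id & side == "L"][1])
        rf <- file.path(input, files[base == id & side == "R"][1])
        preprocess(read_image(lf, mm_per_px), read_image(rf, mm_per_px),
                   channel = channel, kernel_scale = kernel_scale)
      } else {
        img <- read_image(file.path(input, files[ids == id][1]), mm_per_px)
        to_gray(correct_illumination(img, estimate_flatfield(
          if (is_rgb(img)) to_gray(img, "mean") else img, kernel_scale)),
          if (is_rgb(img)) channel else "mean")
      }
      mask <- switch(method,
        adaptive = adaptive_threshold(gray, block_size, proportion, polarity),
        double = double_adaptive_threshold(gray, neighborhood_sizes, min_change, polarity),
        global = global_threshold(gray, global_t, polarity),
        auto = global_threshold(gray, auto_threshold(gray), polarity))
      mask <- clean_mask(mask, min_object_px)
      rep <- measure_mask(mask, prune_px = prune_px, class_edges = class_edges)
      png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                    file.path(output, paste0(id, "_mask.png")))
      lbc <- rep$length_by_class
      names(lbc) <- paste0("length_mm_", names(lbc))
      cbind(data.frame(id = id, total_length_mm = rep$total_length,
                       axile_length_mm = rep$axile_length,
                       lateral_length_mm = rep$lateral_length,
                       mean_diameter_mm = rep$mean_diameter,
                       surface_mm2 = rep$surface, volume_mm3 = rep$volume),
            as.data.frame(as.list(lbc), check.names = FALSE))
    }, error = function(e) {
      logf("ERROR %s: %s", id, conditionMessage(e))
      failures <<- c(failures, id)
      NULL
    })
    if (!is.null(res)) {
      rows[[id]] <- res
      logf("ok %s: total %.2f mm", id, res$total_length_mm)
    }
  }
  report <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
            else empty_report()
  utils::write.csv(report, file.path(output, "report.csv"), row.names = FALSE)
  logf("done: %d ok, %d failed", nrow(report), length(failures))
  if (length(failures))
    warning(length(failures), " image(s) failed; see ", log_path, call. = FALSE)
  invisible(structure(report, failures = failures,
                      paths = list(report = file.path(output, "report.csv"),
                                   log = log_path)))
}

empty_report <- function() {
  data.frame(id = character(), total_length_mm = numeric(),
             axile_length_mm = numeric(), lateral_length_mm = numeric(),
             mean_diameter_mm = numeric(), surface_mm2 = numeric(),
             volume_mm3 = numeric())
}
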