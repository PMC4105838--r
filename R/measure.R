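#' Skeletonize a binary root mask
#'
#' Topology-preserving 8-connected thinning (Zhang-Suen with a sequential
#' cleanup of redundant corner pixels) reducing every mask component to a
#' one-pixel-wide centerline. An empty mask yields an empty skeleton.
#'
#' @param mask a [binary_mask].
#' @return A `skeleton` object (logical matrix with `mm_per_px`).
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sk <- thin_cpp(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  structure(sk, mm_per_px = mm_per_px(mask),
            class = c("skeleton", "binary_mask", "matrix", "array"))
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d x %d px, %.4g mm/px, %d px, length %.2f mm\n",
              nrow(x), ncol(x), mm_per_px(x), sum(x), skeleton_length(x)))
  invisible(x)
}

# 8-neighbour count for every pixel of a logical matrix
neighbor_counts <- function(m) {
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1L
  n <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    n <- n + p[2:(nrow(m) + 1L) + dr, 2:(ncol(m) + 1L) + dc, drop = FALSE]
  }
  n
}

#' Prune short terminal spurs from a skeleton
#'
#' Iteratively removes terminal branches whose chain-code length is below
#' `max_spur_px` and that end at a junction pixel. Such spurs are thinning
#' artefacts of ragged root/background boundaries (root hairs, reflections)
#' and inflate length estimates; isolated paths (both ends free) are never
#' removed, so main-path connectivity is preserved.
#'
#' @param skeleton a `skeleton` from [skeletonize()].
#' @param max_spur_px spurs strictly shorter than this many (chain-code)
#'   pixels are removed; 0 is the identity.
#' @return The pruned `skeleton`.
#' @export
prune <- function(skeleton, max_spur_px = 5) {
  stopifnot(inherits(skeleton, "skeleton"))
  check_number(max_spur_px, "max_spur_px")
  if (max_spur_px < 0) stop_param("max_spur_px must be >= 0")
  if (max_spur_px == 0) return(skeleton)
  m <- matrix(as.logical(skeleton), nrow(skeleton), ncol(skeleton))
  H <- nrow(m); W <- ncol(m)
  drs <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  wts <- sqrt(drs^2 + dcs^2)
  neighbors <- function(r, c) {
    rr <- r + drs; cc <- c + dcs
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    ok[ok] <- m[cbind(rr[ok], cc[ok])]
    list(r = rr[ok], c = cc[ok], w = wts[ok])
  }
  repeat {
    cnt <- neighbor_counts(m)
    ends <- which(m & cnt == 1L, arr.ind = TRUE)
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      r <- ends[e, 1L]; c <- ends[e, 2L]
      if (!m[r, c]) next
      path <- matrix(c(r, c), 1L, 2L)
      plen <- 0
      pr <- -1L; pc <- -1L
      repeat {
        nb <- neighbors(r, c)
        keep <- !(nb$r == pr & nb$c == pc)
        if (sum(keep) != 1L) break          # ambiguous step (touching junction)
        nr <- nb$r[keep]; nc <- nb$c[keep]; w <- nb$w[keep]
        if (cnt[nr, nc] >= 3L) {            # branch ends at a junction
          if (plen + w < max_spur_px) {
            m[path] <- FALSE
            removed_any <- TRUE
          }
          break
        }
        plen <- plen + w
        if (plen >= max_spur_px) break      # long enough to keep
        if (cnt[nr, nc] == 1L) break        # isolated path, keep
        path <- rbind(path, c(nr, nc))
        pr <- r; pc <- c
        r <- nr; c <- nc
      }
    }
    if (!removed_any) break
    # dissolve one-pixel stubs left where a spur attached diagonally to the
    # main path (they are simple points, so re-thinning removes exactly them)
    m <- thin_cpp(m)
  }
  structure(m, mm_per_px = mm_per_px(skeleton),
            class = c("skeleton", "binary_mask", "matrix", "array"))
}

# unique 8-adjacency steps of a skeleton: one row per pixel pair, with the
# chain-code weight (1 orthogonal, sqrt(2) diagonal) and both endpoints'
# linear indices
skeleton_steps <- function(sk) {
  m <- matrix(as.logical(sk), nrow(sk), ncol(sk))
  H <- nrow(m); W <- ncol(m)
  pair_idx <- function(dr, dc) {
    if (H <= abs(dr) || W <= abs(dc)) return(NULL)
    a <- m[seq_len(H - abs(dr)) + max(-dr, 0), seq_len(W - abs(dc)) + max(-dc, 0), drop = FALSE]
    b <- m[seq_len(H - abs(dr)) + max(dr, 0), seq_len(W - abs(dc)) + max(dc, 0), drop = FALSE]
    hit <- which(a & b)
    if (!length(hit)) return(NULL)
    hr <- (hit - 1L) %% (H - abs(dr)) + 1L
    hc <- (hit - 1L) %/% (H - abs(dr)) + 1L
    r1 <- hr + max(-dr, 0); c1 <- hc + max(-dc, 0)
    r2 <- hr + max(dr, 0);  c2 <- hc + max(dc, 0)
    data.frame(i = (c1 - 1L) * H + r1, j = (c2 - 1L) * H + r2,
               w = if (dr != 0 && dc != 0) sqrt(2) else 1)
  }
  out <- rbind(pair_idx(1L, 0L), pair_idx(0L, 1L), pair_idx(1L, 1L), pair_idx(-1L, 1L))
  if (is.null(out)) data.frame(i = integer(), j = integer(), w = numeric()) else out
}

#' Chain-code length of a skeleton
#'
#' Sums every unique 8-adjacent skeleton pixel pair, counting orthogonal
#' steps as one pixel and diagonal steps as sqrt(2) pixels, scaled to mm.
#' Junction pixels contribute once per incident step.
#'
#' @param skeleton a `skeleton` (or any `binary_mask` holding a thinned
#'   centerline).
#' @return Length in mm.
#' @export
skeleton_length <- function(skeleton) {
  stopifnot(inherits(skeleton, "binary_mask"))
  sum(skeleton_steps(skeleton)$w) * mm_per_px(skeleton)
}

#' Per-skeleton-pixel root diameter from the distance transform
#'
#' The local diameter at a skeleton pixel is twice its Euclidean distance to
#' the mask boundary. The distance transform returns the distance to the
#' nearest background pixel centre; the object boundary lies half a pixel
#' closer, so `diameter = (2 * edt - 1) * mm_per_px`.
#'
#' @param mask the [binary_mask] the skeleton was thinned from.
#' @param skeleton the `skeleton`; every skeleton pixel must lie inside the
#'   mask.
#' @return Numeric matrix of diameters in mm (`NA` off the skeleton), with
#'   the pixel size attached.
#' @export
diameter_map <- function(mask, skeleton) {
  stopifnot(inherits(mask, "binary_mask"), inherits(skeleton, "binary_mask"))
  if (!identical(dim(mask), dim(skeleton)))
    stop_param("mask and skeleton differ in shape")
  sk <- matrix(as.logical(skeleton), nrow(skeleton), ncol(skeleton))
  if (any(sk & !as.logical(mask)))
    stop_param("skeleton pixel outside the mask")
  edt <- as.numeric(EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  d[sk] <- (2 * edt[sk] - 1) * mm_per_px(mask)
  attr(d, "mm_per_px") <- mm_per_px(mask)
  d
}

#' Root length by diameter class, with derived surface and volume
#'
#' Assigns every chain-code step of the skeleton to a diameter class by the
#' mean diameter of its two endpoint pixels, and accumulates length per
#' class. With the default single class edge at 0.5 mm, length in classes at
#' or above the edge is reported as axile root length and length below it as
#' lateral root length, the standard large/small diameter split for maize.
#' Surface and volume assume a cylinder per step
#' (`surface = sum(pi * d * L)`, `volume = sum(pi * (d/2)^2 * L)`).
#'
#' @param skeleton a `skeleton`.
#' @param diameters diameter matrix from [diameter_map()].
#' @param class_edges increasing vector of class boundaries in mm.
#' @param axile_min_mm diameter separating lateral from axile length.
#' @return A `measurement_report`: list with `total_length`,
#'   `length_by_class` (named vector, mm), `mean_diameter`, `surface`,
#'   `volume`, `axile_length`, `lateral_length` (mm, mm^2, mm^3).
#' @export
length_by_class <- function(skeleton, diameters, class_edges = 0.5,
                            axile_min_mm = 0.5) {
  stopifnot(inherits(skeleton, "binary_mask"))
  if (length(class_edges) && any(diff(class_edges) <= 0))
    stop_param("class_edges must be strictly increasing")
  steps <- skeleton_steps(skeleton)
  mmpp <- mm_per_px(skeleton)
  if (!nrow(steps)) {
    edges <- c(0, class_edges, Inf)
    lbc <- setNames(numeric(length(edges) - 1L),
                    paste0("[", edges[-length(edges)], ",", edges[-1L], ")"))
    return(structure(list(total_length = 0, length_by_class = lbc,
                          mean_diameter = NA_real_, surface = 0, volume = 0,
                          axile_length = 0, lateral_length = 0),
                     class = "measurement_report"))
  }
  d_step <- (diameters[steps$i] + diameters[steps$j]) / 2
  if (anyNA(d_step)) stop_param("diameters missing at skeleton pixels")
  len <- steps$w * mmpp
  edges <- c(0, class_edges, Inf)
  cls <- findInterval(d_step, edges)
  lbc <- vapply(seq_len(length(edges) - 1L),
                function(k) sum(len[cls == k]), numeric(1))
  names(lbc) <- paste0("[", edges[-length(edges)], ",", edges[-1L], ")")
  structure(list(total_length = sum(len), length_by_class = lbc,
                 mean_diameter = sum(d_step * len) / sum(len),
                 surface = sum(pi * d_step * len),
                 volume = sum(pi * (d_step / 2)^2 * len),
                 axile_length = sum(len[d_step >= axile_min_mm]),
                 lateral_length = sum(len[d_step < axile_min_mm])),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("<measurement_report> total length %.2f mm (axile %.2f, lateral %.2f)\n",
              x$total_length, x$axile_length, x$lateral_length))
  cat(sprintf("  mean diameter %.3f mm, surface %.1f mm^2, volume %.2f mm^3\n",
              x$mean_diameter, x$surface, x$volume))
  cat("  length by diameter class (mm):\n")
  print(round(x$length_by_class, 2))
  invisible(x)
}

#' Surface and volume of root segments under the cylinder model
#'
#' @param segments data frame with columns `length` (mm) and `diameter` (mm).
#' @return List with `surface` (mm^2) and `volume` (mm^3).
#' @export
surface_volume <- function(segments) {
  if (!all(c("length", "diameter") %in% names(segments)))
    stop_param("segments must have columns length and diameter")
  list(surface = sum(pi * segments$diameter * segments$length),
       volume = sum(pi * (segments$diameter / 2)^2 * segments$length))
}

#' Measure a segmented mask end to end
#'
#' Convenience wrapper running [skeletonize()], [prune()], [diameter_map()]
#' and [length_by_class()] on a binary mask.
#'
#' @param mask a [binary_mask].
#' @param prune_px spur-pruning length in px (see [prune()]).
#' @param class_edges diameter class boundaries in mm.
#' @return A `measurement_report` with the pruned `skeleton` and the
#'   diameter matrix attached as attributes `skeleton` and `diameters`.
#' @export
measure_mask <- function(mask, prune_px = 5, class_edges = 0.5) {
  sk <- prune(skeletonize(mask), prune_px)
  d <- diameter_map(mask, sk)
  rep <- length_by_class(sk, d, class_edges)
  attr(rep, "skeleton") <- sk
  attr(rep, "diameters") <- d
  rep
}

#' Image resolution arithmetic
#'
#' `resolution_mm_per_px()` converts an imaged physical width and the sensor
#' pixel count across it into the pixel size; `min_detectable_diameter()`
#' applies the rule that an image-processing software needs at least `k_px`
#' (three, by default) pixels across a root to detect it. At the reference
#' setup (490 mm slide width on a 3744-px sensor axis) the pixel size is
#' 0.13 mm and the minimum detectable diameter 0.39 mm, within the published
#' range of maize lateral root diameters.
#'
#' @param imaged_width_mm physical width covered by the sensor axis, mm.
#' @param sensor_px_across number of sensor pixels across that width.
#' @param mm_per_px pixel size in mm.
#' @param k_px minimum root width in pixels required for detection.
#' @return Pixel size in mm/px, or minimum detectable diameter in mm.
#' @examples
#' resolution_mm_per_px(490, 3744)
#' min_detectable_diameter(0.13)
#' @export
resolution_mm_per_px <- function(imaged_width_mm, sensor_px_across) {
  check_number(imaged_width_mm, "imaged_width_mm", positive = TRUE)
  check_number(sensor_px_across, "sensor_px_across", positive = TRUE)
  imaged_width_mm / sensor_px_across
}

#' @rdname resolution_mm_per_px
#' @export
min_detectable_diameter <- function(mm_per_px, k_px = 3) {
  check_number(mm_per_px, "mm_per_px", positive = TRUE)
  check_number(k_px, "k_px", positive = TRUE)
  k_px * mm_per_px
}
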