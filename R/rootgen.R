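#' Vectorized root systems
#'
#' A `root_system` is the ground-truth object of the toolkit: a list of roots,
#' each an ordered polyline of nodes carrying a position (mm, origin at the
#' top-left corner, y increasing downward to match image row order) and a
#' local diameter (mm). Axile roots have order 0; lateral roots have order 1
#' and name their parent.
#'
#' @param id root identifier (character).
#' @param order 0 for axile, 1 for lateral roots.
#' @param nodes data frame with numeric columns `x`, `y`, `diameter` (mm),
#'   at least two rows, consecutive nodes distinct, diameters > 0.
#' @param parent_id identifier of the parent root (required when `order >= 1`).
#' @param roots list of objects built by `root()`.
#' @param extent bounding box `c(width, height)` in mm; all roots must fit.
#' @param seed integer seed the system was generated from, or `NULL`.
#' @return `root()` a single root; `root_system()` a validated `root_system`.
#' @seealso [generate_root_system()], [render()], [true_length()]
#' @export
root <- function(id, order, nodes, parent_id = NULL) {
  nodes <- as.data.frame(nodes)
  if (!all(c("x", "y", "diameter") %in% names(nodes)))
    stop_param("nodes must have columns x, y, diameter")
  if (nrow(nodes) < 2L) stop_param("root '", id, "' needs at least 2 nodes")
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "diameter")]))))
    stop_param("root '", id, "' has non-finite node values")
  if (any(nodes$diameter <= 0)) stop_param("root '", id, "' has a non-positive diameter")
  dd <- diff(nodes$x)^2 + diff(nodes$y)^2
  if (any(dd == 0)) stop_param("root '", id, "' has coincident consecutive nodes")
  order <- as.integer(order)
  if (order >= 1L && is.null(parent_id))
    stop_param("lateral root '", id, "' has no parent_id")
  structure(list(id = as.character(id), order = order,
                 parent_id = if (is.null(parent_id)) NULL else as.character(parent_id),
                 nodes = nodes[c("x", "y", "diameter")]),
            class = "root")
}

#' @rdname root
#' @export
root_system <- function(roots, extent, seed = NULL) {
  if (!length(roots)) stop_param("a root_system needs at least one root")
  stopifnot(all(vapply(roots, inherits, logical(1), "root")))
  if (length(extent) != 2L || any(!is.finite(extent)) || any(extent <= 0))
    stop_param("extent must be positive c(width, height) in mm")
  for (r in roots) {
    if (any(r$nodes$x < -1e-9) || any(r$nodes$x > extent[1] + 1e-9) ||
        any(r$nodes$y < -1e-9) || any(r$nodes$y > extent[2] + 1e-9))
      stop_param("root '", r$id, "' lies outside the extent")
  }
  names(roots) <- vapply(roots, `[[`, character(1), "id")
  structure(list(roots = roots, extent = as.numeric(extent),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "root_system")
}

#' @export
print.root_system <- function(x, ...) {
  orders <- vapply(x$roots, `[[`, integer(1), "order")
  tl <- true_length(x)
  cat(sprintf("<root_system> %d roots (%d axile, %d lateral), extent %g x %g mm\n",
              length(x$roots), sum(orders == 0L), sum(orders > 0L),
              x$extent[1], x$extent[2]))
  cat(sprintf("  total centerline length %.1f mm%s\n", tl$total_mm,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' @export
plot.root_system <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$extent[1]), ylim = c(x$extent[2], 0),
                 xlab = "x (mm)", ylab = "y (mm)", asp = 1, ...)
  for (r in x$roots) {
    p <- resample_centerline(r, step = 0.5)
    graphics::lines(p$x, p$y, lwd = 1 + 2 * (r$order == 0L),
                    col = if (r$order == 0L) "black" else "grey40")
  }
  invisible(x)
}

# directed random walk used for both axile and lateral roots; heading is the
# angle from the downward vertical (radians), positive toward +x
grow_walk <- function(x0, y0, heading, ds, n_steps, extent, margin,
                      wander_sd, pull) {
  xs <- x0; ys <- y0
  th <- heading
  for (i in seq_len(n_steps)) {
    th <- th + rnorm(1L, 0, wander_sd) - pull * th
    nx <- xs[length(xs)] + ds * sin(th)
    ny <- ys[length(ys)] + ds * cos(th)
    if (nx < margin || nx > extent[1] - margin ||
        ny < margin || ny > extent[2] - margin) break
    xs <- c(xs, nx); ys <- c(ys, ny)
  }
  data.frame(x = xs, y = ys)
}

taper <- function(n, from, to) from + (to - from) * seq(0, 1, length.out = n)

#' Generate a random maize-like root system
#'
#' Draws `n_axile` axile roots as smooth, gravitropic downward random walks
#' from near the top edge of the extent, and attaches lateral roots at random
#' arc-length positions along each axile centerline. Lateral diameters are
#' drawn within 0.26-0.47 mm and axile diameters within 0.6-1.2 mm, the
#' published range for maize grown on germination paper; both taper from base
#' to tip. The first node of every lateral lies exactly on its parent's
#' interpolating spline.
#'
#' @param n_axile number of axile roots (>= 1).
#' @param laterals_per_cm expected number of laterals per cm of axile length.
#' @param extent bounding box `c(width, height)` in mm.
#' @param seed integer seed; identical seeds give identical systems.
#' @return A [root_system].
#' @examples
#' rs <- generate_root_system(n_axile = 2, laterals_per_cm = 1, seed = 1)
#' rs
#' @export
generate_root_system <- function(n_axile = 3, laterals_per_cm = 1.5,
                                 extent = c(60, 80), seed = NULL) {
  check_number(n_axile, "n_axile", positive = TRUE, integer = TRUE)
  check_number(laterals_per_cm, "laterals_per_cm")
  if (laterals_per_cm < 0) stop_param("laterals_per_cm must be >= 0")
  if (length(extent) != 2L || any(!is.finite(extent)) || any(extent <= 0))
    stop_param("extent must be positive c(width, height) in mm")
  margin <- max(1, 0.02 * min(extent))
  with_seed(seed, {
    roots <- list()
    for (i in seq_len(n_axile)) {
      x0 <- extent[1] * (i - 0.5) / n_axile + rnorm(1L, 0, extent[1] * 0.02)
      x0 <- min(max(x0, margin), extent[1] - margin)
      walk <- grow_walk(x0, margin, heading = rnorm(1L, 0, 0.18), ds = 3,
                        n_steps = 200L, extent = extent, margin = margin,
                        wander_sd = 0.06, pull = 0.08)
      if (nrow(walk) < 2L) walk <- data.frame(x = c(x0, x0), y = margin + c(0, 2))
      ax <- root(id = sprintf("A%d", i), order = 0L,
                 nodes = cbind(walk, diameter = taper(nrow(walk), runif(1, 0.85, 1.2),
                                                      runif(1, 0.60, 0.72))))
      roots[[ax$id]] <- ax
      if (laterals_per_cm > 0) {
        dense <- resample_centerline(ax, step = 0.05)
        len_cm <- max(dense$s) / 10
        n_lat <- floor(laterals_per_cm * len_cm) +
          (runif(1) < (laterals_per_cm * len_cm) %% 1)
        if (n_lat < 1) next
        pos <- sort(runif(n_lat, 0.08, 0.92)) * max(dense$s)
        for (j in seq_len(n_lat)) {
          k <- which.min(abs(dense$s - pos[j]))
          k <- min(max(k, 2L), nrow(dense) - 1L)
          tangent <- atan2(dense$x[k + 1] - dense$x[k - 1],
                           dense$y[k + 1] - dense$y[k - 1])
          side <- sample(c(-1, 1), 1L)
          lat_len <- runif(1, 8, 35)
          walk <- grow_walk(dense$x[k], dense$y[k],
                            heading = tangent + side * runif(1, 0.9, 1.4),
                            ds = 2, n_steps = max(2L, round(lat_len / 2)),
                            extent = extent, margin = margin,
                            wander_sd = 0.09, pull = 0.10)
          if (nrow(walk) < 2L) next
          base_d <- runif(1, 0.30, 0.45)
          lat <- root(id = sprintf("%s.L%d", ax$id, j), order = 1L,
                      parent_id = ax$id,
                      nodes = cbind(walk, diameter = taper(nrow(walk), base_d,
                                                           runif(1, 0.26, min(0.30, base_d)))))
          roots[[lat$id]] <- lat
        }
      }
    }
    root_system(roots, extent, seed)
  })
}

#' Resample a root centerline on its interpolating spline
#'
#' Interpolates the node polyline with a natural cubic spline (parameterized
#' by cumulative chord length; linear for two-node roots), evaluated densely
#' enough that consecutive points are at most `step` mm apart. Endpoints are
#' preserved exactly and node diameters are interpolated linearly along the
#' parameter.
#'
#' @param root a [root()] object.
#' @param step maximum spacing between returned points, in mm.
#' @return Data frame with columns `x`, `y`, `diameter` and `s` (cumulative
#'   arc length in mm, starting at 0).
#' @export
resample_centerline <- function(root, step = 0.1) {
  stopifnot(inherits(root, "root"))
  check_number(step, "step", positive = TRUE)
  nd <- root$nodes
  t <- c(0, cumsum(sqrt(diff(nd$x)^2 + diff(nd$y)^2)))
  total <- t[length(t)]
  # oversample the parameter grid: arc spacing can locally exceed the chord
  # parameter spacing on curved splines
  m <- max(2L, ceiling(1.25 * total / step) + 1L)
  tt <- seq(0, total, length.out = m)
  if (nrow(nd) == 2L) {
    x <- approx(t, nd$x, xout = tt)$y
    y <- approx(t, nd$y, xout = tt)$y
  } else {
    x <- spline(t, nd$x, xout = tt, method = "natural")$y
    y <- spline(t, nd$y, xout = tt, method = "natural")$y
  }
  d <- approx(t, nd$diameter, xout = tt)$y
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  data.frame(x = x, y = y, diameter = d, s = s)
}

#' Ground-truth root length from the spline model
#'
#' Arc length of every root's interpolating spline, the quantity measured
#' estimates are scored against. Additive over roots and stable under
#' resampling refinement (halving `step` changes the total by < 0.1%).
#'
#' @param system a [root_system].
#' @param step resampling step in mm used for arc-length integration.
#' @return List with `total_mm` and a per-root data frame `per_root`
#'   (columns `id`, `order`, `length_mm`, `mean_diameter_mm`).
#' @export
true_length <- function(system, step = 0.05) {
  stopifnot(inherits(system, "root_system"))
  per <- lapply(system$roots, function(r) {
    p <- resample_centerline(r, step = step)
    data.frame(id = r$id, order = r$order, length_mm = max(p$s),
               mean_diameter_mm = mean(p$diameter))
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  list(total_mm = sum(per$length_mm), per_root = per)
}
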