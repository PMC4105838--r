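# shared fixtures and independent oracles, all built in code

# straight vertical root of given length/diameter centred in a 60x80 mm scene
straight_system <- function(length_mm = 70, diameter = 0.8, x = 30, y0 = 5) {
  r <- root("A1", 0L, data.frame(x = c(x, x), y = c(y0, y0 + length_mm),
                                 diameter = diameter))
  root_system(list(r), c(60, 80))
}

# n nodes on a circle of radius r spanning `span` radians (arc length r*span)
arc_root <- function(n_nodes = 5, radius = 20, span = pi / 2,
                     centre = c(25, 25)) {
  th <- seq(0, span, length.out = n_nodes)
  root("C1", 0L, data.frame(x = centre[1] + radius * sin(th),
                            y = centre[2] + radius * (1 - cos(th)),
                            diameter = 0.5))
}

# seeded random 8-bit grayscale image
random_image <- function(seed, nr = 40, nc = 50, mm = 0.13) {
  with_seed <- get("with_seed", envir = asNamespace("rootraster"))
  with_seed(seed, raster_image(matrix(sample(0:255, nr * nc, TRUE), nr, nc), mm))
}

# grayscale -> RGB raster by channel replication
gray_to_rgb <- function(img) {
  a <- array(unclass(img), c(dim(img), 3L))
  raster_image(a, mm_per_px(img), bit_depth(img))
}

# minimum distance from point p = c(x, y) to the polyline (xs, ys), projecting
# onto every segment
dist_point_polyline <- function(p, xs, ys) {
  ax <- xs[-length(xs)]; ay <- ys[-length(ys)]
  vx <- diff(xs); vy <- diff(ys)
  t <- ((p[1] - ax) * vx + (p[2] - ay) * vy) / (vx^2 + vy^2)
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((ax + t * vx - p[1])^2 + (ay + t * vy - p[2])^2))
}

# brute-force 8-connected component labelling (flood fill), the oracle for
# clean_mask component counts
label_components_oracle <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1L)
    lab[i, j] <- cur
    while (nrow(queue)) {
      q <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        r <- q[1] + dr; c <- q[2] + dc
        if (r < 1 || c < 1 || r > nrow(m) || c > ncol(m)) next
        if (m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# brute-force chain-code length: enumerate unordered 8-adjacent pixel pairs
chain_length_oracle <- function(sk) {
  px <- which(sk, arr.ind = TRUE)
  total <- 0
  if (nrow(px) < 2) return(0)
  for (a in seq_len(nrow(px) - 1L)) for (b in (a + 1L):nrow(px)) {
    dr <- abs(px[a, 1] - px[b, 1]); dc <- abs(px[a, 2] - px[b, 2])
    if (dr <= 1 && dc <= 1) total <- total + sqrt(dr^2 + dc^2)
  }
  unname(total * mm_per_px(sk))
}

# half-amplitude width (in px) of a 1-D cross-section profile, by linear
# interpolation of the two half-maximum crossings
half_amp_width <- function(profile, background, amplitude) {
  half <- background + amplitude / 2
  above <- which(profile > half)
  if (!length(above)) return(0)
  lo <- min(above); hi <- max(above)
  left <- if (lo == 1) lo else
    lo - (profile[lo] - half) / (profile[lo] - profile[lo - 1])
  right <- if (hi == length(profile)) hi else
    hi + (profile[hi] - half) / (profile[hi] - profile[hi + 1])
  right - left
}

# the acceptance benchmark is shared by two criteria; compute it once
.acceptance_env <- new.env(parent = emptyenv())
acceptance_benchmark <- function() {
  if (is.null(.acceptance_env$bm))
    .acceptance_env$bm <- run_benchmark(n_systems = 10, seed = 42)
  .acceptance_env$bm
}
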