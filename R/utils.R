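# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(structure(class = c("rootraster_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a single finite number")
  if (positive && x <= 0) stop_param(name, " must be > 0")
  if (integer && x != round(x)) stop_param(name, " must be an integer")
  invisible(x)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Mean over a square window of odd-ish size `size` (clipped at borders), via
# summed-area tables. Used by the adaptive and double-adaptive thresholds and
# by the smoothed block-mean variant.
box_mean <- function(m, size) {
  check_number(size, "size", positive = TRUE, integer = TRUE)
  h <- floor(size / 2)
  nr <- nrow(m); nc <- ncol(m)
  if (size > max(nr, nc)) stop_param("window size exceeds both image dimensions")
  # summed-area table with a zero border
  S <- matrix(0, nr + 1L, nc + 1L)
  cc <- apply(m, 2L, cumsum)
  if (nr == 1L) cc <- matrix(cc, 1L, nc)
  S[-1L, -1L] <- if (nc == 1L) cc else t(apply(cc, 1L, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  # sums over [r1..r2] x [c1..c2] for every pixel
  A <- S[cbind(rep(r2 + 1L, nc), rep(c2 + 1L, each = nr))]
  B <- S[cbind(rep(r1, nc),      rep(c2 + 1L, each = nr))]
  C <- S[cbind(rep(r2 + 1L, nc), rep(c1, each = nr))]
  D <- S[cbind(rep(r1, nc),      rep(c1, each = nr))]
  counts <- (r2 - r1 + 1L) %o% (c2 - c1 + 1L)
  matrix((A - B - C + D), nr, nc) / counts
}
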