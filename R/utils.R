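#' @keywords internal
"_PACKAGE"

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All stochastic generators in the
## package route through this so no function touches global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a stream-specific sub-seed so that per-window / per-particle
## streams are independent but fully determined by the user's seed.
sub_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483629L
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("evcoloc_validation_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("evcoloc_format_error", "error")))
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

## Minimum distance from each point to a set of line segments.
## points: n x 2; segs: m x 4 (x1, y1, x2, y2). Returns length-n vector.
## Vectorized over segments; points are chunked by the caller if needed.
point_segment_distance <- function(points, segs) {
  n <- nrow(points)
  if (n == 0L) return(numeric(0))
  if (is.null(segs) || nrow(segs) == 0L) return(rep(Inf, n))
  dx <- segs[, 3] - segs[, 1]
  dy <- segs[, 4] - segs[, 2]
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- .Machine$double.eps
  out <- numeric(n)
  ## chunk so the n_chunk x m temporary stays modest
  chunk <- max(1L, floor(4e6 / nrow(segs)))
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    px <- points[idx, 1]
    py <- points[idx, 2]
    wx <- outer(px, segs[, 1], "-")
    wy <- outer(py, segs[, 2], "-")
    t <- sweep(sweep(wx, 2, dx, "*") + sweep(wy, 2, dy, "*"), 2, len2, "/")
    t[t < 0] <- 0
    t[t > 1] <- 1
    ex <- wx - sweep(t, 2, dx, "*")
    ey <- wy - sweep(t, 2, dy, "*")
    d2 <- ex * ex + ey * ey
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}
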