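# Shared fixtures and independent oracles, built in code at test time.

# Signed area of a closed polyline (shoelace).
shoelace_area <- function(p) {
  abs(sum(p[-nrow(p), 1] * p[-1, 2] - p[-1, 1] * p[-nrow(p), 2])) / 2
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# Small standard scene used across modules: 4 filaments in a 6.4 um field.
small_scene <- function(seed = 3) {
  filament_scene(4, field = c(6400, 6400), half_width = 100, seed = seed)
}

# Naive KDE oracle: per-pixel double loop over spots, same pixel-center
# evaluation and per-axis box truncation rule as the rendered map.
naive_probability_map <- function(records, pixel, A, trunc, nr, nc) {
  acc <- matrix(0, nr, nc)
  n <- nrow(records)
  for (i in seq_len(n)) {
    sd <- A * records$uncertainty[i]
    r <- trunc * sd
    for (col in seq_len(nc)) {
      xc <- (col - 0.5) * pixel
      if (abs(xc - records$x[i]) > r) next
      for (row in seq_len(nr)) {
        yc <- (row - 0.5) * pixel
        if (abs(yc - records$y[i]) > r) next
        acc[row, col] <- acc[row, col] +
          dnorm(xc, records$x[i], sd) * dnorm(yc, records$y[i], sd)
      }
    }
  }
  acc / n
}

# Exhaustive Otsu oracle: scans the same candidate grid, computing each
# class variance directly.
otsu_oracle <- function(v, n_candidates = 256) {
  v <- as.numeric(v)
  theta <- seq(min(v), max(v), length.out = n_candidates)
  pop_var <- function(x) if (length(x) == 0L) 0 else mean((x - mean(x))^2)
  crit <- vapply(theta, function(th) {
    s_in <- v[v >= th]
    s_out <- v[v < th]
    (length(s_in) * pop_var(s_in) + length(s_out) * pop_var(s_out)) / length(v)
  }, numeric(1))
  theta[which.min(crit)]
}

# Supersampled distance-transform oracle for signed distances: the boundary
# is approximated by the centers of supersampled pixels adjacent to the
# opposite class; sign from the containing (original) pixel.
signed_distance_oracle <- function(points, mask, supersample = 4) {
  m <- mask$values
  k <- supersample
  big <- m[rep(seq_len(nrow(m)), each = k), rep(seq_len(ncol(m)), each = k)]
  padded <- matrix(0L, nrow(big) + 2L, ncol(big) + 2L)
  padded[2:(nrow(big) + 1L), 2:(ncol(big) + 1L)] <- big
  interface <- matrix(FALSE, nrow(big), ncol(big))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- padded[2:(nrow(big) + 1L) + dr, 2:(ncol(big) + 1L) + dc]
    interface <- interface | (big == 1L & nb == 0L)
  }
  idx <- which(interface, arr.ind = TRUE)
  ssp <- mask$pixel / k
  bx <- mask$origin[1] + (idx[, 2] - 0.5) * ssp
  by <- mask$origin[2] + (idx[, 1] - 0.5) * ssp
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt(min((bx - points[i, 1])^2 + (by - points[i, 2])^2))
    cc <- min(floor((points[i, 1] - mask$origin[1]) / mask$pixel) + 1L, ncol(m))
    rr <- min(floor((points[i, 2] - mask$origin[2]) / mask$pixel) + 1L, nrow(m))
    if (m[rr, cc] == 1L) -d else d
  }, numeric(1))
}

# Three long fibrils that never approach within 0.9 um of each other
# (asserted below): boundary-distance recovery is only meaningful where
# structures are resolvable, i.e. separated by more than the kernel blur.
coloc_scene <- function() {
  sc <- filament_scene(3, field = c(9600, 9600), half_width = 200,
                       curvature = 0.08, length = 9000, n_segments = 30,
                       seed = 45)
  for (i in 1:2) for (j in (i + 1):3) {
    v <- sc$filaments[[j]]$vertices
    segs <- cbind(v[-nrow(v), , drop = FALSE], v[-1, , drop = FALSE])
    stopifnot(min(evcoloc:::point_segment_distance(
      sc$filaments[[i]]$vertices, segs)) > 900)
  }
  sc
}

# Segmented movie over a synthetic scene: shared input for coloc tests.
# Returns scene, movie, segmentation, boundaries and the window scheme.
build_scene_movie <- function(scene, n_windows = 10, W = 300, S = 6,
                              blink = blink_model(per_frame_density = 0.1),
                              seed = 11) {
  T <- W + n_windows * S
  tab <- sample_localizations(scene, blink, n_frames = T, seed = seed)
  scheme <- window_scheme(T = T, W = W, S = S)
  movie <- build_movie(tab, scheme, render_params(), field = scene$field)
  seg <- segment_movie(movie)
  bounds <- lapply(seg$masks, extract_boundaries)
  list(scene = scene, scheme = scheme, movie = movie, seg = seg,
       masks = seg$masks, bounds = bounds)
}
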