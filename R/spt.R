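#' Image frame stack
#'
#' Ordered single-channel image frames with pixel size (nm) and frame rate.
#'
#' @param images List of numeric matrices of identical dimensions.
#' @param pixel Pixel size in nm.
#' @param frame_rate Frames per second (> 0).
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(images, pixel, frame_rate = 30) {
  stopifnot(is.list(images), length(images) >= 1L)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop_validation("all frames must share the same dimensions")
  if (frame_rate <= 0) stop_validation("frame_rate must be > 0")
  structure(list(images = images, pixel = pixel, frame_rate = frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("frame_stack: %d frame(s) of %d x %d px @ %.1f nm, %.1f frames/s\n",
              length(x$images), d[1], d[2], x$pixel, x$frame_rate))
  invisible(x)
}

#' Rolling (sliding-window) frame average
#'
#' Output frame t is the mean of input frames `[t, t + n - 1]`; the output
#' has `T - n + 1` frames.
#'
#' @param stack A [frame_stack()].
#' @param n Window length in frames (1 <= n <= T).
#' @return A `frame_stack` of averaged frames.
#' @export
rolling_average <- function(stack, n) {
  stopifnot(inherits(stack, "frame_stack"))
  T <- length(stack$images)
  if (!is_count(n, 1)) stop_validation("n must be a positive integer")
  if (n > T) stop_validation("window n (%d) exceeds stack length (%d)", n, T)
  out <- lapply(seq_len(T - n + 1L), function(t) {
    Reduce(`+`, stack$images[t:(t + n - 1L)]) / n
  })
  frame_stack(out, stack$pixel, stack$frame_rate)
}

#' Non-overlapping block frame average
#'
#' Averages consecutive non-overlapping blocks of `n` frames, converting a
#' 200 frames/s acquisition to 33.3 frames/s for n = 6 — the conversion
#' used to synchronize the particle channel with the dSTORM movie. Trailing
#' frames that do not fill a block are dropped.
#'
#' @inheritParams rolling_average
#' @return A `frame_stack` of `floor(T / n)` averaged frames, with the
#'   frame rate divided by `n`.
#' @export
block_average <- function(stack, n) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!is_count(n, 1)) stop_validation("n must be a positive integer")
  n_blocks <- length(stack$images) %/% n
  if (n_blocks < 1L) stop_validation("stack shorter than one block")
  out <- lapply(seq_len(n_blocks), function(b) {
    Reduce(`+`, stack$images[((b - 1L) * n + 1L):(b * n)]) / n
  })
  frame_stack(out, stack$pixel, stack$frame_rate / n)
}

#' 3 x 3 neighborhood smoothing
#'
#' Replaces each pixel by the mean of its 3 x 3 neighborhood; at the image
#' edge the truncated in-bounds neighborhood is used (the ImageJ "Smooth"
#' convention).
#'
#' @param image Numeric matrix, at least 3 x 3.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth3x3 <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop_validation("image must be at least 3 x 3")
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      r_src <- max(1L, 1L - dr):min(nr, nr - dr)
      c_src <- max(1L, 1L - dc):min(nc, nc - dc)
      acc[r_src + dr, c_src + dc] <- acc[r_src + dr, c_src + dc] +
        image[r_src, c_src]
      cnt[r_src + dr, c_src + dc] <- cnt[r_src + dr, c_src + dc] + 1
    }
  }
  acc / cnt
}

#' Detect fluorescent spots in an image
#'
#' Finds local maxima strictly above `threshold`, applies non-maximum
#' suppression within `min_separation` pixels (brighter peaks win), and
#' localizes each detection by the intensity-weighted centroid of the 5 x 5
#' window around the peak.
#'
#' @param image Numeric matrix.
#' @param threshold Intensity cutoff (e.g. the free-dye intensity): only
#'   maxima with value > threshold are detections.
#' @param min_separation Minimum peak separation in pixels (default 3).
#' @param pixel Pixel size in nm; centroids are reported in nm (default 1,
#'   i.e. pixel units).
#' @param frame Frame index stored with each detection.
#' @return data.frame with columns `frame`, `x`, `y` (centroid, nm),
#'   `peak_intensity`, `integrated_intensity`.
#' @export
detect_spots <- function(image, threshold, min_separation = 3, pixel = 1,
                         frame = 1L) {
  if (threshold < 0) stop_validation("threshold must be >= 0")
  nr <- nrow(image); nc <- ncol(image)
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      peak_intensity = numeric(),
                      integrated_intensity = numeric())
  ## local maximum: >= all 8 neighbors (out-of-bounds treated as -Inf)
  is_max <- image > threshold
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      shifted <- matrix(-Inf, nr, nc)
      r_src <- max(1L, 1L - dr):min(nr, nr - dr)
      c_src <- max(1L, 1L - dc):min(nc, nc - dc)
      shifted[r_src + dr, c_src + dc] <- image[r_src, c_src]
      is_max <- is_max & (image >= shifted)
    }
  }
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0L) return(empty)
  vals <- image[peaks]
  ord <- order(-vals, peaks[, 1], peaks[, 2])
  peaks <- peaks[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(peaks))
  taken_r <- numeric(0); taken_c <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    if (length(taken_r) == 0L ||
        all(pmax(abs(taken_r - peaks[i, 1]),
                 abs(taken_c - peaks[i, 2])) >= min_separation)) {
      keep[i] <- TRUE
      taken_r <- c(taken_r, peaks[i, 1])
      taken_c <- c(taken_c, peaks[i, 2])
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  vals <- vals[keep]
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks[i, 1]; cc <- peaks[i, 2]
    rs <- max(1L, r - 2L):min(nr, r + 2L)
    cs <- max(1L, cc - 2L):min(nc, cc + 2L)
    w <- image[rs, cs, drop = FALSE]
    w <- pmax(w, 0)
    s <- sum(w)
    if (s <= 0) {
      cx <- cc; cy <- r
    } else {
      cy <- sum(rowSums(w) * rs) / s
      cx <- sum(colSums(w) * cs) / s
    }
    c(cx, cy, s)
  })
  res <- do.call(rbind, res)
  data.frame(frame = frame,
             x = (res[, 1] - 0.5) * pixel,
             y = (res[, 2] - 0.5) * pixel,
             peak_intensity = vals,
             integrated_intensity = res[, 3])
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor linking: candidate (track end, detection) pairs
#' within `max_disp` are assigned in ascending-distance order; unmatched
#' detections seed new tracks; a track survives up to `max_gap` consecutive
#' missing frames.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (nm) and
#'   optionally `peak_intensity` — e.g. [detect_spots()] output row-bound
#'   over frames.
#' @param max_disp Maximum displacement (nm) per linked step.
#' @param max_gap Maximum missing frames bridged within a track (default 2).
#' @return data.frame with columns `track_id`, `frame`, `x`, `y`,
#'   `intensity`, sorted by (track_id, frame).
#' @export
link_tracks <- function(detections, max_disp = 500, max_gap = 2) {
  if (nrow(detections) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), intensity = numeric()))
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  inten <- if (is.null(detections$peak_intensity)) rep(NA_real_, nrow(detections)) else detections$peak_intensity
  frames <- sort(unique(detections$frame))
  ## active tracks: id, last x/y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 1L
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    idx <- which(detections$frame == f)
    dx <- detections$x[idx]; dy <- detections$y[idx]
    ## expire tracks beyond the gap
    live <- act_f >= f - max_gap - 1L
    act_id <- act_id[live]; act_x <- act_x[live]; act_y <- act_y[live]
    act_f <- act_f[live]
    assigned <- rep(NA_integer_, length(idx))
    if (length(act_id) > 0L && length(idx) > 0L) {
      dmat <- sqrt(outer(act_x, dx, "-")^2 + outer(act_y, dy, "-")^2)
      cand <- which(dmat <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_t <- logical(length(act_id))
        for (k in seq_len(nrow(cand))) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (!used_t[ti] && is.na(assigned[di])) {
            used_t[ti] <- TRUE
            assigned[di] <- ti
          }
        }
      }
    }
    ids <- integer(length(idx))
    for (j in seq_along(idx)) {
      if (is.na(assigned[j])) {
        ids[j] <- next_id
        next_id <- next_id + 1L
        act_id <- c(act_id, ids[j]); act_x <- c(act_x, dx[j])
        act_y <- c(act_y, dy[j]); act_f <- c(act_f, f)
      } else {
        ti <- assigned[j]
        ids[j] <- act_id[ti]
        act_x[ti] <- dx[j]; act_y[ti] <- dy[j]; act_f[ti] <- f
      }
    }
    out[[fi]] <- data.frame(track_id = ids, frame = f, x = dx, y = dy,
                            intensity = inten[idx])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Brightest pixel within a region
#'
#' Returns the argmax pixel of `image` restricted to `region`; ties break
#' to the smallest (row, col).
#'
#' @param image Numeric matrix.
#' @param region Either a logical matrix the size of `image` or an n x 2
#'   matrix of (row, col) pixel indices; must be nonempty.
#' @return `c(row, col)` of the brightest pixel.
#' @export
brightest_point <- function(image, region) {
  if (is.logical(region)) {
    region <- which(region, arr.ind = TRUE)
  }
  region <- rbind(region)
  if (nrow(region) == 0L) stop_validation("empty region")
  vals <- image[region]
  mx <- max(vals)
  cand <- region[vals == mx, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  c(row = cand[1, 1], col = cand[1, 2])
}
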