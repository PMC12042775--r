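#' Otsu threshold on map values
#'
#' Determines the threshold separating in-structure from background map
#' values by minimizing the count-weighted average of the two intraclass
#' variances (equivalently, maximizing the between-class variance). With
#' classes `S_in = {v >= theta}` and `S_out = {v < theta}` of sizes `N_in`,
#' `N_out`, the criterion is
#' `(N_in * var(S_in) + N_out * var(S_out)) / (N_in + N_out)`
#' (population variances). Candidate thresholds are `n_candidates` equally
#' spaced values spanning `[min(v), max(v)]`; ties are broken toward the
#' smallest threshold.
#'
#' @param values Numeric vector (or matrix) of map values; at least two
#'   distinct values are required.
#' @param n_candidates Number of candidate thresholds (default 256).
#' @param keep_curve Retain the full criterion curve? Default TRUE.
#' @return Object of class `otsu_result`: `theta_hat`, `n_candidates`, and
#'   (optionally) `criterion_curve` (data.frame `theta`, `criterion`).
#' @export
otsu_threshold <- function(values, n_candidates = 256, keep_curve = TRUE) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop(errorCondition("constant input: histogram is degenerate",
                        class = c("evcoloc_degenerate_histogram",
                                  "evcoloc_validation_error", "error")))
  sv <- sort(v)
  n <- length(sv)
  cs1 <- cumsum(sv)
  cs2 <- cumsum(sv^2)
  tot1 <- cs1[n]
  tot2 <- cs2[n]
  theta <- seq(min(sv), max(sv), length.out = n_candidates)
  ## m = |S_out| = #{v < theta}
  m <- findInterval(theta, sv, left.open = TRUE)
  sum_out <- ifelse(m > 0L, cs1[pmax(m, 1L)], 0)
  sum_out[m == 0L] <- 0
  n_in <- n - m
  ## N * criterion = total sum of squares - sum_out^2/m - sum_in^2/(n - m)
  ss_out <- ifelse(m > 0L, sum_out^2 / pmax(m, 1L), 0)
  ss_in <- ifelse(n_in > 0L, (tot1 - sum_out)^2 / pmax(n_in, 1L), 0)
  criterion <- (tot2 - ss_out - ss_in) / n
  best <- which.min(criterion)   # first minimum = smallest theta
  structure(list(theta_hat = theta[best],
                 n_candidates = n_candidates,
                 criterion = criterion[best],
                 criterion_curve = if (keep_curve)
                   data.frame(theta = theta, criterion = criterion)),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("otsu_result: theta_hat = %.6g over %d candidates (criterion %.4g)\n",
              x$theta_hat, x$n_candidates, x$criterion))
  invisible(x)
}

new_binary_mask <- function(values, pixel, origin = c(0, 0),
                            threshold = NA_real_,
                            window_index = NA_integer_) {
  structure(list(values = values, pixel = pixel, origin = origin,
                 threshold = threshold, window_index = window_index),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px @ %.1f nm, %.1f%% in-structure\n",
              nrow(x$values), ncol(x$values), x$pixel,
              100 * mean(x$values)))
  invisible(x)
}

#' Binarize a probability map
#'
#' A pixel is in-structure iff its map value is `>= theta` (the boundary
#' case is classified as structure so the degenerate two-value histogram
#' remains classifiable).
#'
#' @param map A `prob_map`.
#' @param theta Finite threshold.
#' @return A `binary_mask` with values in {0, 1}.
#' @export
binarize <- function(map, theta) {
  stopifnot(inherits(map, "prob_map"), is.finite(theta))
  v <- matrix(as.integer(map$values >= theta),
              nrow(map$values), ncol(map$values))
  new_binary_mask(v, map$pixel, map$origin, threshold = theta,
                  window_index = map$window_index)
}

#' Segment a dSTORM movie with a single pooled threshold
#'
#' One Otsu threshold is computed from the map values pooled across all
#' movie frames (a single threshold per video) and applied to every frame.
#' Above `cap` pooled values, a uniform stride subsample is thresholded;
#' below the cap the pooled computation is exact.
#'
#' @param movie A `dstorm_movie` (or plain list of `prob_map`s), nonempty.
#' @param n_candidates Candidate thresholds for [otsu_threshold()].
#' @param cap Maximum number of pooled values (default 2e7).
#' @return Object of class `segmented_movie`: list with `otsu` (the
#'   [otsu_threshold()] result) and `masks` (list of `binary_mask`).
#' @export
segment_movie <- function(movie, n_candidates = 256, cap = 2e7) {
  if (length(movie) == 0L) stop_validation("movie is empty")
  pooled <- unlist(lapply(movie, function(m) as.numeric(m$values)),
                   use.names = FALSE)
  if (length(pooled) > cap) {
    pooled <- pooled[seq(1L, length(pooled), by = ceiling(length(pooled) / cap))]
  }
  ot <- otsu_threshold(pooled, n_candidates, keep_curve = FALSE)
  masks <- lapply(movie, binarize, theta = ot$theta_hat)
  structure(list(otsu = ot, masks = masks), class = "segmented_movie")
}

#' @export
print.segmented_movie <- function(x, ...) {
  cat(sprintf("segmented_movie: %d mask(s), theta_hat = %.6g\n",
              length(x$masks), x$otsu$theta_hat))
  invisible(x)
}

#' Extract sub-pixel structure boundaries
#'
#' Traces the contours of a binary mask by marching squares at level 0.5 on
#' the {0, 1} pixel grid (via the base contouring routine), yielding
#' sub-pixel polylines in nm. The grid is zero-padded by one pixel so every
#' contour — including structures touching the field edge — closes.
#'
#' @param mask A `binary_mask`.
#' @return Object of class `boundary_set`: list with `polylines` (each an
#'   n x 2 closed matrix of nm coordinates), `pixel` and `window_index`. An
#'   empty mask yields an empty polyline list.
#' @export
extract_boundaries <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values
  if (all(m == 0L)) {
    return(structure(list(polylines = list(), pixel = mask$pixel,
                          window_index = mask$window_index),
                     class = "boundary_set"))
  }
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- m
  ## contourLines takes z[i, j] at (x[i], y[j]): transpose so x varies along
  ## columns of the mask. Pixel (r, c) center is at ((c - 0.5)p, (r - 0.5)p).
  xc <- mask$origin[1] + ((0:(nc + 1L)) - 0.5) * mask$pixel
  yc <- mask$origin[2] + ((0:(nr + 1L)) - 0.5) * mask$pixel
  cl <- grDevices::contourLines(x = xc, y = yc, z = t(padded), levels = 0.5)
  polylines <- lapply(cl, function(ct) {
    p <- cbind(ct$x, ct$y)
    if (nrow(p) >= 2L && any(p[1L, ] != p[nrow(p), ])) {
      p <- rbind(p, p[1L, ])   # close the loop
    }
    p
  })
  polylines <- polylines[vapply(polylines, nrow, integer(1)) >= 2L]
  structure(list(polylines = polylines, pixel = mask$pixel,
                 window_index = mask$window_index),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("boundary_set: %d polyline(s), %d vertices total\n",
              length(x$polylines),
              sum(vapply(x$polylines, nrow, integer(1)))))
  invisible(x)
}

## All boundary polyline segments as an m x 4 matrix (x1, y1, x2, y2).
boundary_segments <- function(boundaries) {
  if (length(boundaries$polylines) == 0L) return(NULL)
  do.call(rbind, lapply(boundaries$polylines, function(p) {
    cbind(p[-nrow(p), , drop = FALSE], p[-1L, , drop = FALSE])
  }))
}
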