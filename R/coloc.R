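#' Signed distance from points to structure boundaries
#'
#' The magnitude is the minimum Euclidean distance from the point to any
#' boundary polyline segment; the sign is negative iff the point's
#' containing pixel is in-structure (inside an ECM structure). With an
#' empty boundary set every distance is `+Inf` (flagged via attribute
#' `empty_boundary`).
#'
#' @param points n x 2 matrix of nm coordinates; all inside the mask field.
#' @param mask A `binary_mask`.
#' @param boundaries A `boundary_set` derived from `mask` (see
#'   [extract_boundaries()]); computed on the fly if missing.
#' @return Numeric vector of signed distances in nm.
#' @export
signed_distance <- function(points, mask, boundaries = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  points <- rbind(points)
  if (nrow(points) == 0L) return(numeric(0))
  nr <- nrow(mask$values); nc <- ncol(mask$values)
  px <- points[, 1] - mask$origin[1]
  py <- points[, 2] - mask$origin[2]
  cc <- pmin(floor(px / mask$pixel) + 1L, nc)
  rr <- pmin(floor(py / mask$pixel) + 1L, nr)
  if (any(px < 0 | py < 0 | px > nc * mask$pixel | py > nr * mask$pixel))
    stop_validation("point(s) outside the mask field")
  if (is.null(boundaries)) boundaries <- extract_boundaries(mask)
  segs <- boundary_segments(boundaries)
  if (is.null(segs)) {
    out <- rep(Inf, nrow(points))
    attr(out, "empty_boundary") <- TRUE
    return(out)
  }
  d <- point_segment_distance(points, segs)
  inside <- mask$values[cbind(rr, cc)] == 1L
  d[inside] <- -d[inside]
  d
}

#' Signed distances for all (window, particle) pairs
#'
#' For every reconstruction window and every track with a detection at the
#' synchronized particle-movie frame, computes one signed boundary
#' distance. Missing detections are skipped and counted in the `skipped`
#' attribute.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y` (nm);
#'   `frame` is indexed in averaged particle-movie frames.
#' @param masks List of `binary_mask`, one per window.
#' @param boundaries List of `boundary_set`, parallel to `masks`.
#' @param sync Integer vector from [sync_index()]: for each window, the
#'   averaged particle-movie frame paired with it.
#' @return data.frame of class `signed_distances` with columns `track_id`,
#'   `window`, `distance`.
#' @export
pair_distances <- function(tracks, masks, boundaries, sync) {
  if (length(sync) != length(masks) || length(masks) != length(boundaries))
    stop_validation("sync, masks and boundaries must have one entry per window")
  skipped <- 0L
  out <- vector("list", length(masks))
  for (k in seq_along(masks)) {
    sel <- tracks$frame == sync[k]
    if (!any(sel)) {
      skipped <- skipped + 1L
      next
    }
    pts <- cbind(tracks$x[sel], tracks$y[sel])
    d <- signed_distance(pts, masks[[k]], boundaries[[k]])
    out[[k]] <- data.frame(track_id = tracks$track_id[sel], window = k,
                           distance = as.numeric(d))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(track_id = integer(), window = integer(),
                      distance = numeric())
  rownames(res) <- NULL
  attr(res, "skipped_windows") <- skipped
  class(res) <- c("signed_distances", "data.frame")
  res
}

#' Histogram of signed boundary distances
#'
#' Bins distances at a fixed 50-nm width over `range`, with half-open bins
#' `[lo, hi)`. Relative frequencies are over in-range records; out-of-range
#' records are tallied separately, never silently dropped. The raw in-range
#' values are retained for bootstrap resampling.
#'
#' @param distances Numeric vector of signed distances (nm), or a
#'   `signed_distances` data.frame.
#' @param range `c(lo, hi)` in nm; both must be multiples of the bin width.
#'   Default `c(-300, 600)`.
#' @param width Bin width in nm (default 50, the analysis convention).
#' @return Object of class `dist_histogram`: `bin_edges`, `counts`,
#'   `rel_freq`, `n_total`, `n_out_of_range`, `values`.
#' @export
distance_histogram <- function(distances, range = c(-300, 600), width = 50) {
  if (is.data.frame(distances)) distances <- distances$distance
  if (any(range %% width != 0))
    stop_validation("range endpoints must be multiples of the bin width")
  edges <- seq(range[1], range[2], by = width)
  d <- distances[is.finite(distances)]
  n_nonfinite <- length(distances) - length(d)
  in_range <- d >= range[1] & d < range[2]
  v <- d[in_range]
  bin <- findInterval(v, edges)   # [lo, hi) half-open
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  n_in <- sum(counts)
  structure(list(bin_edges = edges, counts = counts,
                 rel_freq = if (n_in > 0) counts / n_in else counts * 0,
                 n_total = length(distances),
                 n_out_of_range = sum(!in_range) + n_nonfinite,
                 values = v),
            class = "dist_histogram")
}

#' @export
print.dist_histogram <- function(x, ...) {
  cat(sprintf("dist_histogram: %d bin(s) of %.0f nm over [%.0f, %.0f), %d in-range / %d total\n",
              length(x$counts), diff(x$bin_edges[1:2]), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts), x$n_total))
  invisible(x)
}

#' Null-model signed distances from uniform random spots
#'
#' Emulates the computer-generated random-spot null: `n_per_window` points
#' uniform over the analysis region per window, each assigned its signed
#' boundary distance for that window's segmentation.
#'
#' @param masks List of `binary_mask`, one per window.
#' @param boundaries Parallel list of `boundary_set`.
#' @param region Analysis region passed to [uniform_points()]: `c(w, h)` nm
#'   rectangle (default: full mask field) or a `binary_mask` ROI.
#' @param n_per_window Random spots per window (default 1000).
#' @param seed Integer seed (per-window streams derived from it).
#' @return `signed_distances` data.frame (`track_id` is the spot index).
#' @export
null_distances <- function(masks, boundaries, region = NULL,
                           n_per_window = 1000, seed = 1) {
  stopifnot(length(masks) == length(boundaries))
  out <- vector("list", length(masks))
  for (k in seq_along(masks)) {
    reg <- if (is.null(region)) {
      m <- masks[[k]]
      c(ncol(m$values), nrow(m$values)) * m$pixel
    } else {
      region
    }
    pts <- uniform_points(reg, n_per_window, seed = sub_seed(seed, k))
    d <- signed_distance(pts, masks[[k]], boundaries[[k]])
    out[[k]] <- data.frame(track_id = seq_len(n_per_window), window = k,
                           distance = as.numeric(d))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("signed_distances", "data.frame")
  res
}

#' Normalized relative frequency with bootstrap confidence intervals
#'
#' The headline colocalization statistic: the per-bin ratio of the observed
#' relative frequency of particle-boundary distances to that of uniformly
#' random spots. A ratio exceeding 1 indicates enrichment of particles at
#' that distance from the structure edge. Bins where the null frequency is
#' zero are flagged undefined (`NA` ratio), never silently zero. The
#' percentile bootstrap CI resamples the observed records (the null is held
#' fixed).
#'
#' @param obs,null `dist_histogram`s on identical bin edges.
#' @param bootstrap_n Bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `norm_freq`: data.frame with columns `bin_lo`,
#'   `bin_hi`, `obs_freq`, `null_freq`, `ratio`, `ci_lo`, `ci_hi`,
#'   `defined`, plus attributes recording the bootstrap spec.
#' @export
normalize_frequency <- function(obs, null, bootstrap_n = 1000, level = 0.95,
                                seed = 1) {
  stopifnot(inherits(obs, "dist_histogram"), inherits(null, "dist_histogram"))
  if (!isTRUE(all.equal(obs$bin_edges, null$bin_edges)))
    stop_validation("observed and null histograms have mismatched binning")
  defined <- null$rel_freq > 0
  ratio <- ifelse(defined, obs$rel_freq / null$rel_freq, NA_real_)
  nb <- length(obs$counts)
  ci <- matrix(NA_real_, nb, 2)
  nv <- length(obs$values)
  if (nv > 0L && bootstrap_n > 0L) {
    boot <- with_seed(seed, {
      reps <- matrix(NA_real_, bootstrap_n, nb)
      for (b in seq_len(bootstrap_n)) {
        res <- obs$values[sample.int(nv, nv, replace = TRUE)]
        bin <- findInterval(res, obs$bin_edges)
        cnt <- tabulate(bin, nbins = nb)
        reps[b, ] <- (cnt / nv) / null$rel_freq
      }
      reps
    })
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    for (j in which(defined)) {
      ci[j, ] <- stats::quantile(boot[, j], probs, names = FALSE)
    }
  }
  out <- data.frame(bin_lo = obs$bin_edges[-(nb + 1L)],
                    bin_hi = obs$bin_edges[-1L],
                    obs_freq = obs$rel_freq,
                    null_freq = null$rel_freq,
                    ratio = ratio,
                    ci_lo = ci[, 1], ci_hi = ci[, 2],
                    defined = defined)
  attr(out, "bootstrap") <- list(n = bootstrap_n, level = level, seed = seed)
  class(out) <- c("norm_freq", "data.frame")
  out
}

#' Mean enrichment over a distance range
#'
#' Average of the normalized relative frequency over the bins covering
#' `range` (defined bins only) — e.g. the near-edge window of -100 to
#' 150 nm where enrichment is biologically meaningful.
#'
#' @param nf A `norm_freq`.
#' @param range `c(lo, hi)` in nm.
#' @return Mean ratio over defined bins intersecting the range.
#' @export
mean_enrichment <- function(nf, range = c(-100, 150)) {
  sel <- nf$bin_lo < range[2] & nf$bin_hi > range[1] & nf$defined
  if (!any(sel)) return(NA_real_)
  mean(nf$ratio[sel])
}
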