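#' Sliding reconstruction window scheme
#'
#' Defines the pseudo real-time movie scheme: reconstruction windows of `W`
#' frames over a `T`-frame acquisition, each shifted by `S` frames. With the
#' defaults (W = 1002, S = 6) a 3,504-frame acquisition yields 417 windows.
#'
#' @param T Total acquisition frames.
#' @param W Window length in frames (default 1002).
#' @param S Step between consecutive windows in frames (default 6).
#' @return Object of class `window_scheme`.
#' @export
window_scheme <- function(T, W = 1002, S = 6) {
  if (!is_count(T, 1) || !is_count(W, 1) || !is_count(S, 1))
    stop_validation("T, W, S must be positive integers")
  if (W > T) stop_validation("window length W (%d) exceeds total frames T (%d)", W, T)
  structure(list(T = as.integer(T), W = as.integer(W), S = as.integer(S)),
            class = "window_scheme")
}

#' Window start frames
#'
#' Start frames are `1 + k*S` for `k = 0 ... n-1` with
#' `n = floor((T - W) / S)`; window k covers frames `[start, start + W - 1]`.
#' Note the deliberate convention: the count is `floor((T - W)/S)`, not
#' `+ 1`, so the final window that would still fit is dropped; this matches
#' the one-window-per-averaged-particle-frame pairing of the synchronized
#' two-channel movie (3,504 frames -> 417 windows).
#'
#' @param scheme A [window_scheme()].
#' @return Integer vector of start frames (possibly empty).
#' @export
window_starts <- function(scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  n <- (scheme$T - scheme$W) %/% scheme$S
  if (n < 1L) return(integer(0))
  1L + (0:(n - 1L)) * scheme$S
}

#' Filter localizations by uncertainty
#'
#' Drops spots with extremely small or large localization uncertainties
#' (likely noise, e.g. camera shot noise); retains `u_min <= u <= u_max`.
#' Rejection counts are recorded in the `filter` attribute.
#'
#' @param table A [loc_table()].
#' @param u_min,u_max Uncertainty bounds in nm. Defaults 2 and 100.
#' @return Filtered `loc_table`.
#' @export
filter_uncertainty <- function(table, u_min = 2, u_max = 100) {
  stopifnot(inherits(table, "loc_table"))
  if (!(u_min < u_max)) stop_validation("require u_min < u_max")
  keep <- table$records$uncertainty >= u_min & table$records$uncertainty <= u_max
  out <- table
  out$records <- table$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "filter") <- list(u_min = u_min, u_max = u_max,
                              n_rejected = sum(!keep), n_kept = sum(keep))
  out
}

#' Reconstruction rendering parameters
#'
#' @param pixel Reconstruction pixel size in nm (default 10).
#' @param A Kernel scale coefficient: each spot's Gaussian kernel has SD
#'   `A * uncertainty` (default 6, the empirically estimated scale).
#' @param truncation_radius Kernel truncation, in kernel SDs, applied per
#'   axis (default 4; per-kernel mass error < 1.3e-4).
#' @param u_min,u_max Uncertainty filter bounds in nm.
#' @param background A [background_model()].
#' @param display_sigma Fixed Gaussian SD (nm) for display rendering only
#'   (default 24); never used for segmentation.
#' @return Object of class `render_params`.
#' @export
render_params <- function(pixel = 10, A = 6, truncation_radius = 4,
                          u_min = 2, u_max = 100,
                          background = background_model(),
                          display_sigma = 24) {
  if (pixel <= 0 || A <= 0 || truncation_radius <= 0)
    stop_validation("pixel, A and truncation_radius must be positive")
  if (!(u_min < u_max)) stop_validation("require u_min < u_max")
  structure(list(pixel = pixel, A = A,
                 truncation_radius = truncation_radius,
                 u_min = u_min, u_max = u_max,
                 background = background, display_sigma = display_sigma),
            class = "render_params")
}

#' Background mixture model for the existence-probability map
#'
#' The map is `alpha * (spot average) + (1 - alpha) * background`, where the
#' background is either a constant `mu_bg` or per-pixel draws from
#' N(mu_bg, sigma_bg^2) (`mode = "sampled"`). The default `alpha = 1` uses
#' no explicit background term.
#'
#' @param alpha Mixture weight in [0, 1].
#' @param mu_bg,sigma_bg Background mean and SD.
#' @param mode `"constant"` or `"sampled"`.
#' @param seed Seed for sampled mode.
#' @return Object of class `background_model`.
#' @export
background_model <- function(alpha = 1, mu_bg = 0, sigma_bg = 0,
                             mode = c("constant", "sampled"), seed = 1) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha > 1) stop_validation("alpha must be in [0, 1]")
  if (sigma_bg < 0) stop_validation("sigma_bg must be >= 0")
  structure(list(alpha = alpha, mu_bg = mu_bg, sigma_bg = sigma_bg,
                 mode = mode, seed = seed),
            class = "background_model")
}

new_prob_map <- function(values, pixel, origin = c(0, 0),
                         window_index = NA_integer_,
                         frame_span = c(NA_integer_, NA_integer_)) {
  structure(list(values = values, pixel = pixel, origin = origin,
                 window_index = window_index, frame_span = frame_span),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("prob_map: %d x %d px @ %.1f nm", nrow(x$values),
              ncol(x$values), x$pixel))
  if (!is.na(x$window_index))
    cat(sprintf(", window %d (frames %d-%d)", x$window_index,
                x$frame_span[1], x$frame_span[2]))
  cat(sprintf(", mass %.4g\n", sum(x$values) * x$pixel^2))
  invisible(x)
}

## Core kernel accumulator. Each spot contributes a Gaussian of SD
## sd_i = A * u_i evaluated at pixel centers, truncated per axis at
## truncation_radius * sd_i (the naive oracle uses the same box rule).
## Returns the *sum* of kernels; callers normalize.
accumulate_kernels <- function(x, y, sd, nr, nc, pixel, origin, trunc) {
  acc <- matrix(0, nr, nc)
  if (length(x) == 0L) return(acc)
  for (i in seq_along(x)) {
    r <- trunc * sd[i]
    xi <- x[i] - origin[1]
    yi <- y[i] - origin[2]
    c0 <- max(1L, floor((xi - r) / pixel) + 1L)
    c1 <- min(nc, floor((xi + r) / pixel) + 1L)
    r0 <- max(1L, floor((yi - r) / pixel) + 1L)
    r1 <- min(nr, floor((yi + r) / pixel) + 1L)
    if (c0 > c1 || r0 > r1) next
    xc <- ((c0:c1) - 0.5) * pixel
    yc <- ((r0:r1) - 0.5) * pixel
    gx <- stats::dnorm(xc, xi, sd[i])
    gx[abs(xc - xi) > r] <- 0
    gy <- stats::dnorm(yc, yi, sd[i])
    gy[abs(yc - yi) > r] <- 0
    acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + outer(gy, gx)
  }
  acc
}

#' Existence-probability map of one reconstruction window
#'
#' Renders the kernel-density existence-probability map: each localization i
#' spreads into an isotropic Gaussian centered at (x_i, y_i) with SD
#' `A * u_i` (u_i the per-spot uncertainty); the map is the average of the N
#' unit-mass kernels evaluated at pixel centers, optionally mixed with a
#' background term:
#' `p = alpha * (1/N) * sum_i p_i + (1 - alpha) * p_bg`.
#' With N = 0 the map is pure background. Values are probability densities
#' in nm^-2: `sum(values) * pixel^2` is approximately 1 for alpha = 1 when
#' no kernel is clipped by the field edge.
#'
#' @param locs A [loc_table()], already uncertainty-filtered.
#' @param params A [render_params()].
#' @param field Field size in nm `c(width, height)`; the grid covers it.
#' @param origin Grid origin in nm.
#' @param window_index,frame_span Bookkeeping stored in the result.
#' @return A `prob_map`.
#' @export
probability_map <- function(locs, params, field, origin = c(0, 0),
                            window_index = NA_integer_,
                            frame_span = c(NA_integer_, NA_integer_)) {
  stopifnot(inherits(locs, "loc_table"), inherits(params, "render_params"))
  nc <- ceiling(field[1] / params$pixel)
  nr <- ceiling(field[2] / params$pixel)
  r <- locs$records
  bg <- params$background
  sum_k <- accumulate_kernels(r$x, r$y, params$A * r$uncertainty,
                              nr, nc, params$pixel, origin,
                              params$truncation_radius)
  n <- nrow(r)
  spot_term <- if (n > 0L) sum_k / n else matrix(0, nr, nc)
  bg_term <- if (bg$alpha < 1) {
    if (bg$mode == "constant") {
      matrix(bg$mu_bg, nr, nc)
    } else {
      with_seed(bg$seed,
                matrix(stats::rnorm(nr * nc, bg$mu_bg, bg$sigma_bg), nr, nc))
    }
  } else {
    0
  }
  values <- bg$alpha * spot_term + (1 - bg$alpha) * bg_term
  new_prob_map(values, params$pixel, origin, window_index, frame_span)
}

#' Build the sliding-window dSTORM movie
#'
#' One existence-probability map per reconstruction window, in
#' [window_starts()] order. Maps are mutually independent (no temporal
#' smoothing); consecutive windows share `W - S` frames of localizations.
#'
#' @param table A [loc_table()] covering the scheme's frame range.
#' @param scheme A [window_scheme()].
#' @param params A [render_params()]; its uncertainty filter is applied once
#'   to the whole table before windowing.
#' @param field Field size in nm.
#' @return Object of class `dstorm_movie`: list of `prob_map`s with the
#'   scheme and parameters attached as attributes.
#' @export
build_movie <- function(table, scheme, params, field) {
  stopifnot(inherits(table, "loc_table"), inherits(scheme, "window_scheme"))
  tab <- filter_uncertainty(table, params$u_min, params$u_max)
  r <- tab$records[order(tab$records$frame), , drop = FALSE]
  starts <- window_starts(scheme)
  maps <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    lo <- findInterval(s - 0.5, r$frame) + 1L
    hi <- findInterval(s + scheme$W - 1L + 0.5, r$frame)
    win <- tab
    win$records <- if (hi >= lo) r[lo:hi, , drop = FALSE] else r[0, , drop = FALSE]
    maps[[k]] <- probability_map(win, params, field,
                                 window_index = k,
                                 frame_span = c(s, s + scheme$W - 1L))
  }
  structure(maps, scheme = scheme, params = params, field = field,
            class = "dstorm_movie")
}

#' @export
print.dstorm_movie <- function(x, ...) {
  sch <- attr(x, "scheme")
  cat(sprintf("dstorm_movie: %d window(s) of %d frames, step %d\n",
              length(x), sch$W, sch$S))
  invisible(x)
}

#' Fixed-sigma display rendering
#'
#' Conventional Gaussian rendering for display: every localization is
#' splatted with a fixed SD (default 24 nm localization precision),
#' unweighted and unnormalized (total mass = N up to truncation). Display
#' only — segmentation always uses [probability_map()].
#'
#' @param locs A [loc_table()].
#' @param field Field size in nm.
#' @param pixel Pixel size in nm (default 10).
#' @param sigma Rendering SD in nm (default 24).
#' @param origin Grid origin in nm.
#' @return A `prob_map` carrying the rendered image.
#' @export
render_display <- function(locs, field, pixel = 10, sigma = 24,
                           origin = c(0, 0)) {
  stopifnot(inherits(locs, "loc_table"))
  nc <- ceiling(field[1] / pixel)
  nr <- ceiling(field[2] / pixel)
  r <- locs$records
  values <- accumulate_kernels(r$x, r$y, rep(sigma, nrow(r)),
                               nr, nc, pixel, origin, trunc = 4) * pixel^2
  new_prob_map(values, pixel, origin)
}

#' Synchronize dSTORM windows with the averaged particle movie
#'
#' The single-particle channel is converted to the movie frame rate by
#' averaging non-overlapping blocks of `avg_block` original frames (200 to
#' 33.3 frames/s for blocks of 6). Window t is paired with the averaged
#' frame whose center original frame is nearest the window's middle frame
#' (`start + (W - 1)/2`), ties broken to the earlier frame. Exact alignment
#' requires `avg_block == S`, in which case consecutive windows advance by
#' exactly one averaged frame.
#'
#' @param scheme A [window_scheme()].
#' @param avg_block Frames per averaged particle-movie frame; must equal
#'   `scheme$S`.
#' @return Integer vector: for each window, the 1-based averaged-frame
#'   index.
#' @export
sync_index <- function(scheme, avg_block = 6) {
  stopifnot(inherits(scheme, "window_scheme"))
  if (avg_block != scheme$S)
    stop_validation(paste("avg_block (%d) must equal the window step S (%d):",
                          "otherwise window centers and averaged-frame centers",
                          "drift apart and no exact pairing exists"),
                    avg_block, scheme$S)
  starts <- window_starts(scheme)
  centers <- starts + (scheme$W - 1) / 2
  n_blocks <- scheme$T %/% avg_block
  ## block b covers original frames [(b-1)*n + 1, b*n]; center b*n - (n-1)/2
  block_centers <- seq_len(n_blocks) * avg_block - (avg_block - 1) / 2
  vapply(centers, function(cc) {
    d <- abs(block_centers - cc)
    which(d == min(d))[1L]   # tie -> earlier block
  }, integer(1))
}
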