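#' Count particles in one imaging field
#'
#' The standard counting preprocessing: average the first `avg_n` frames
#' (rolling average, first output frame), smooth each pixel by its 3 x 3
#' neighborhood, then detect spots whose intensity exceeds the free-dye
#' reference — only particles brighter than an unbound fluorophore are
#' counted.
#'
#' @param stack A [frame_stack()] with at least `avg_n` frames.
#' @param free_dye_intensity Intensity threshold: the brightness of a free
#'   (unbound) dye molecule, measured upstream.
#' @param avg_n Frames averaged (default 10).
#' @param condition Substrate label (e.g. "laminin", "casein").
#' @param image_id Identifier for this field.
#' @param min_separation Passed to [detect_spots()].
#' @return Object of class `field_count`: `condition`, `image_id`,
#'   `raw_count`, `field_area` (um^2) and the `detections` data.frame.
#' @export
count_field <- function(stack, free_dye_intensity, avg_n = 10,
                        condition = NA_character_, image_id = NA_character_,
                        min_separation = 3) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$images) < avg_n)
    stop_validation("stack has %d frame(s), needs >= avg_n = %d",
                    length(stack$images), avg_n)
  avg <- rolling_average(stack, avg_n)$images[[1L]]
  sm <- smooth3x3(avg)
  det <- detect_spots(sm, threshold = free_dye_intensity,
                      min_separation = min_separation, pixel = stack$pixel)
  area_um2 <- prod(dim(sm)) * stack$pixel^2 / 1e6
  structure(list(condition = condition, image_id = image_id,
                 raw_count = nrow(det), field_area = area_um2,
                 detections = det),
            class = "field_count")
}

#' @export
print.field_count <- function(x, ...) {
  cat(sprintf("field_count: %d particle(s) in %.1f um^2%s\n", x$raw_count,
              x$field_area,
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")))
  invisible(x)
}

count_values <- function(counts) {
  if (inherits(counts, "field_count")) counts <- list(counts)
  vapply(counts, function(cc) {
    if (inherits(cc, "field_count")) cc$raw_count else as.numeric(cc)
  }, numeric(1))
}

#' Net binding above the casein background
#'
#' Specific binding is estimated by subtracting the mean count on
#' casein-coated glass (nonspecific adhesion) from the mean count on
#' ECM-coated glass. The SE combines both groups in quadrature; a negative
#' net count is reported as-is.
#'
#' @param counts_ecm,counts_casein Numeric count vectors or lists of
#'   [count_field()] results; both nonempty.
#' @return List with `net` (mean difference), `se`, `mean_ecm`,
#'   `mean_casein`, `n_ecm`, `n_casein`.
#' @export
net_binding <- function(counts_ecm, counts_casein) {
  e <- count_values(counts_ecm)
  cs <- count_values(counts_casein)
  if (length(e) == 0L || length(cs) == 0L)
    stop_validation("both count lists must be nonempty")
  se_of <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  list(net = mean(e) - mean(cs),
       se = sqrt(se_of(e)^2 + se_of(cs)^2),
       mean_ecm = mean(e), mean_casein = mean(cs),
       n_ecm = length(e), n_casein = length(cs))
}

#' Fit the dilution-series calibration curve
#'
#' Particle counts track the dilution factor df as `count = a / df`
#' (proportional through the origin); `a` is the least-squares coefficient.
#' The curve standardizes EV concentrations across preparations.
#'
#' @param df Dilution factors (>= 1), at least two distinct values.
#' @param count Counts, parallel to `df`.
#' @return Object of class `calibration_curve`: `a`, `points` (per-df mean
#'   and SE), `residuals`.
#' @export
fit_calibration <- function(df, count) {
  if (length(df) != length(count))
    stop_validation("df and count must have the same length")
  if (any(df < 1)) stop_validation("dilution factors must be >= 1")
  if (length(unique(df)) < 2L)
    stop_validation("need at least two distinct dilution factors")
  x <- 1 / df
  a <- sum(count * x) / sum(x * x)
  if (all(count == 0)) warning("all counts are zero; calibration a = 0")
  se_of <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  pts <- do.call(rbind, lapply(sort(unique(df)), function(d) {
    v <- count[df == d]
    data.frame(df = d, mean_count = mean(v), se = se_of(v), n = length(v))
  }))
  structure(list(a = a, points = pts, residuals = count - a * x),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: count = %.4g / df (over df = %s)\n",
              x$a, paste(x$points$df, collapse = ", ")))
  invisible(x)
}

#' Estimate a particle concentration from a field count
#'
#' Counts are proportional to concentration, so
#' `concentration = reference_concentration * count / a` with `a` the
#' calibration coefficient at the reference concentration.
#'
#' @param count A [count_field()] result or a bare count.
#' @param calibration A [fit_calibration()] result with `a > 0`.
#' @param reference_concentration Particles/ml of the undiluted (df = 1)
#'   calibration suspension.
#' @return Estimated concentration in particles/ml.
#' @export
estimate_concentration <- function(count, calibration,
                                   reference_concentration) {
  stopifnot(inherits(calibration, "calibration_curve"))
  if (calibration$a <= 0)
    stop_validation("calibration coefficient must be > 0")
  n <- count_values(count)
  reference_concentration * n / calibration$a
}

#' Two-channel antibody colocalization ratio
#'
#' For each particle detected in channel 1, sums the channel-2 intensity
#' within a disk of `radius` pixels (inclusive: pixels whose centers lie
#' within `radius` of the spot center) and calls the particle colocalized
#' iff that sum exceeds the intensity of a single reference fluorophore
#' molecule. Spots whose disk is truncated by the field edge are flagged.
#'
#' @param spot_centers n x 2 matrix of (row, col) pixel coordinates of
#'   channel-1 particle centers (e.g. from [brightest_point()]); nonempty.
#' @param image2 Channel-2 image matrix.
#' @param radius Disk radius in pixels (default 3).
#' @param single_molecule_intensity Reference single-molecule intensity.
#' @return Object of class `coloc_ratio`: `n_spots`, `n_colocalized`,
#'   `percent`, `radius`, `reference_intensity`, `n_truncated`,
#'   `disk_sums`.
#' @export
antibody_coloc <- function(spot_centers, image2, radius = 3,
                           single_molecule_intensity) {
  spot_centers <- rbind(spot_centers)
  if (nrow(spot_centers) == 0L) stop_validation("spot list must be nonempty")
  nr <- nrow(image2); nc <- ncol(image2)
  dd <- seq(-floor(radius), floor(radius))
  disk <- expand.grid(dr = dd, dc = dd)
  disk <- disk[sqrt(disk$dr^2 + disk$dc^2) <= radius, , drop = FALSE]
  sums <- numeric(nrow(spot_centers))
  truncated <- logical(nrow(spot_centers))
  for (i in seq_len(nrow(spot_centers))) {
    r <- round(spot_centers[i, 1]); cc <- round(spot_centers[i, 2])
    rr <- r + disk$dr; ccc <- cc + disk$dc
    ok <- rr >= 1L & rr <= nr & ccc >= 1L & ccc <= nc
    truncated[i] <- any(!ok)
    sums[i] <- sum(image2[cbind(rr[ok], ccc[ok])])
  }
  colocalized <- sums > single_molecule_intensity
  structure(list(n_spots = nrow(spot_centers),
                 n_colocalized = sum(colocalized),
                 percent = 100 * mean(colocalized),
                 radius = radius,
                 reference_intensity = single_molecule_intensity,
                 n_truncated = sum(truncated),
                 disk_sums = sums),
            class = "coloc_ratio")
}

#' @export
print.coloc_ratio <- function(x, ...) {
  cat(sprintf("coloc_ratio: %d / %d spots colocalized (%.1f%%) at radius %g px\n",
              x$n_colocalized, x$n_spots, x$percent, x$radius))
  invisible(x)
}
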