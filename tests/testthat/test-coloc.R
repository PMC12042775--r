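disk_mask <- function(radius_px = 50, n = 128, pixel = 10) {
  xc <- (seq_len(n) - 0.5); yc <- (seq_len(n) - 0.5)
  d <- sqrt(outer(yc - n / 2, xc - n / 2, function(a, b) a^2 + b^2))
  evcoloc:::new_binary_mask(matrix(as.integer(d <= radius_px), n, n), pixel)
}

test_that("signed distance has the stated sign convention and geometry", {
  mask <- disk_mask(radius_px = 50)   # disk of radius 500 nm, center (640, 640)
  b <- extract_boundaries(mask)
  d_center <- signed_distance(cbind(640, 640), mask, b)
  expect_lt(abs(d_center - (-500)), 10)

  # a point on the boundary polyline is at distance ~0
  v <- b$polylines[[1]][1, , drop = FALSE]
  expect_lt(abs(signed_distance(v, mask, b)), 1e-9)

  # sign convention holds for every record
  pts <- uniform_points(c(1280, 1280), 400, seed = 2)
  d <- signed_distance(pts, mask, b)
  rr <- floor(pts[, 2] / 10) + 1; cc <- floor(pts[, 1] / 10) + 1
  inside <- mask$values[cbind(rr, cc)] == 1L
  expect_true(all((d < 0) == inside))

  expect_error(signed_distance(cbind(2000, 2000), mask, b),
               class = "evcoloc_validation_error")

  # empty boundary set -> +Inf sentinel, flagged
  empty <- evcoloc:::new_binary_mask(matrix(0L, 5, 5), 10)
  d0 <- signed_distance(cbind(25, 25), empty, extract_boundaries(empty))
  expect_true(is.infinite(d0[1]))
  expect_true(attr(d0, "empty_boundary"))
})

test_that("signed distance agrees with a supersampled distance-transform oracle", {
  set.seed(13)
  m <- matrix(0L, 64, 64)
  m[10:30, 8:20] <- 1L
  m[35:60, 30:55] <- 1L
  m[5:15, 40:60] <- 1L
  mask <- evcoloc:::new_binary_mask(m, 10)
  b <- extract_boundaries(mask)
  pts <- uniform_points(c(640, 640), 200, seed = 5)
  d <- signed_distance(pts, mask, b)
  oracle <- signed_distance_oracle(pts, mask)
  expect_lt(max(abs(d - oracle)), 10)  # within one 10-nm pixel
})

test_that("pair_distances records one distance per window and particle", {
  mask <- disk_mask()
  b <- extract_boundaries(mask)
  masks <- rep(list(mask), 10)
  bounds <- rep(list(b), 10)
  tracks <- data.frame(track_id = 1L, frame = 1:10, x = 640, y = 340)
  res <- pair_distances(tracks, masks, bounds, sync = 1:10)
  expect_equal(nrow(res), 10)
  expect_equal(length(unique(res$distance)), 1)

  # bookkeeping: sum over windows of particles present
  tracks2 <- rbind(tracks,
                   data.frame(track_id = 2L, frame = 4:8, x = 200, y = 200))
  res2 <- pair_distances(tracks2, masks, bounds, sync = 1:10)
  expect_equal(nrow(res2), 10 + 5)

  # windows with no detection are skipped and counted
  res3 <- pair_distances(tracks[tracks$frame <= 7, ], masks, bounds,
                         sync = 1:10)
  expect_equal(attr(res3, "skipped_windows"), 3L)
})

test_that("distance histograms use half-open 50-nm bins", {
  h <- distance_histogram(c(-75))
  i <- which(h$bin_edges == -100)
  expect_equal(h$rel_freq[i], 1)
  expect_equal(sum(h$counts), 1)

  set.seed(1)
  d <- runif(500, -290, 590)
  h2 <- distance_histogram(d)
  expect_equal(sum(h2$rel_freq), 1)
  expect_equal(h2$n_out_of_range, 0)

  # boundary value falls in the right-hand bin: [lo, hi)
  h3 <- distance_histogram(c(0, -1e-9))
  expect_equal(h3$counts[which(h3$bin_edges == 0)], 1)
  expect_equal(h3$counts[which(h3$bin_edges == -50)], 1)

  h4 <- distance_histogram(c(-400, 700, 100))
  expect_equal(h4$n_out_of_range, 2)
  expect_equal(h4$n_total, 3)

  empty <- distance_histogram(numeric(0))
  expect_equal(empty$n_total, 0)
  expect_true(all(empty$rel_freq == 0))

  expect_error(distance_histogram(1:10, range = c(-325, 600)),
               class = "evcoloc_validation_error")
})

test_that("null distances are seeded, sized and sign-calibrated", {
  mask <- disk_mask()
  b <- extract_boundaries(mask)
  masks <- rep(list(mask), 4)
  bounds <- rep(list(b), 4)
  n1 <- null_distances(masks, bounds, n_per_window = 200, seed = 3)
  n2 <- null_distances(masks, bounds, n_per_window = 200, seed = 3)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), 4 * 200)
  expect_equal(as.integer(table(n1$window)), rep(200L, 4))

  # fraction of negative distances matches the mask area fraction (binomial)
  nn <- null_distances(masks, bounds, n_per_window = 2000, seed = 4)
  p_hat <- mean(nn$distance < 0)
  p <- mean(mask$values)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / nrow(nn)))
})

test_that("normalization is exactly 1 for identical histograms", {
  set.seed(2)
  d <- runif(2000, -290, 590)
  h <- distance_histogram(d)
  nf <- normalize_frequency(h, h, bootstrap_n = 200, seed = 1)
  expect_true(all(nf$ratio[nf$defined] == 1))
  expect_true(all(nf$defined))

  other <- distance_histogram(d, range = c(-300, 550))
  expect_error(normalize_frequency(h, other),
               class = "evcoloc_validation_error")

  # undefined bins are flagged, not zero
  sparse <- distance_histogram(runif(50, 0, 40))
  nf2 <- normalize_frequency(distance_histogram(runif(50, -290, 590)), sparse,
                             bootstrap_n = 50, seed = 1)
  expect_true(any(!nf2$defined))
  expect_true(all(is.na(nf2$ratio[!nf2$defined])))
})

test_that("doubling the null size changes frequencies only within Monte Carlo error", {
  mask <- disk_mask()
  b <- extract_boundaries(mask)
  masks <- rep(list(mask), 5); bounds <- rep(list(b), 5)
  h1 <- distance_histogram(null_distances(masks, bounds, n_per_window = 1500,
                                          seed = 7))
  h2 <- distance_histogram(null_distances(masks, bounds, n_per_window = 3000,
                                          seed = 8))
  n1 <- sum(h1$counts); n2 <- sum(h2$counts)
  for (j in seq_along(h1$counts)) {
    p <- (h1$counts[j] + h2$counts[j]) / (n1 + n2)
    se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    if (p > 0) expect_lt(abs(h1$rel_freq[j] - h2$rel_freq[j]), 4 * se + 1e-12)
  }
})

test_that("planted bound particles concentrate near the segmented boundary", {
  sm <- build_scene_movie(coloc_scene(), n_windows = 8,
                          blink = blink_model(per_frame_density = 0.5),
                          seed = 21)
  sync <- sync_index(sm$scheme)
  tr <- simulate_tracks(sm$scene, 40, fraction_bound = 1,
                        n_frames = max(sync), dt = 0.03, seed = 121)
  res <- pair_distances(tr, sm$masks, sm$bounds, sync)
  expect_gte(mean(res$distance >= -100 & res$distance <= 100), 0.9)
})
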