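test_that("filament scenes are deterministic, bounded and handle the empty case", {
  empty <- filament_scene(0, field = c(10000, 10000), seed = 1)
  expect_length(empty$filaments, 0)
  expect_equal(empty$total_length, 0)

  a <- filament_scene(5, field = c(25600, 25600), seed = 7)
  b <- filament_scene(5, field = c(25600, 25600), seed = 7)
  expect_identical(a$filaments, b$filaments)

  for (seed in 1:5) {
    sc <- filament_scene(5, field = c(25600, 25600), seed = seed)
    for (f in sc$filaments) {
      expect_true(all(f$vertices[, 1] >= 0 & f$vertices[, 1] <= 25600))
      expect_true(all(f$vertices[, 2] >= 0 & f$vertices[, 2] <= 25600))
    }
  }
  expect_error(filament_scene(-1, seed = 1), class = "evcoloc_validation_error")
  expect_error(filament_scene(2, half_width = -5, seed = 1),
               class = "evcoloc_validation_error")
})

test_that("localization sampling follows the stated Poisson rates", {
  sc <- small_scene()
  bm <- blink_model(per_frame_density = 0.05, false_rate = 0)
  expected <- 0.05 * sc$total_length / 1000 * 200
  for (seed in 1:5) {
    tab <- sample_localizations(sc, bm, n_frames = 200, seed = seed)
    expect_lt(abs(nrow(tab$records) - expected), 4 * sqrt(expected))
    expect_true(all(tab$records$uncertainty > 0))
  }

  # empty cases
  silent <- blink_model(per_frame_density = 0, false_rate = 0)
  expect_equal(nrow(sample_localizations(sc, silent, 50, seed = 1)$records), 0)
  bare <- filament_scene(0, field = c(5000, 5000), seed = 1)
  expect_equal(nrow(sample_localizations(bare, silent, 50, seed = 1)$records), 0)

  # chi-square goodness of fit of per-seed totals over 20 seeds
  lambda <- 0.05 * sc$total_length / 1000 * 100
  totals <- vapply(1:20, function(s) {
    nrow(sample_localizations(sc, bm, n_frames = 100, seed = s)$records)
  }, numeric(1))
  stat <- sum((totals - lambda)^2 / lambda)
  expect_lt(stat, qchisq(0.99, df = 20))
})

test_that("false localizations are uniform and labeled in the truth table", {
  sc <- small_scene()
  bm <- blink_model(per_frame_density = 0.05, false_rate = 0.002)
  tab <- sample_localizations(sc, bm, n_frames = 300, seed = 2)
  truth <- attr(tab, "truth")
  expect_equal(nrow(truth), nrow(tab$records))
  expect_gt(sum(!truth$structure), 0)
  # structure-labeled true positions lie on the filament body
  d <- scene_signed_distance(sc, cbind(truth$true_x[truth$structure],
                                       truth$true_y[truth$structure]))
  expect_true(all(d <= 1e-6))
})

test_that("EV track simulation honors binding fraction and diffusion law", {
  sc <- small_scene()
  tr0 <- simulate_tracks(sc, 30, fraction_bound = 0, n_frames = 20, seed = 1)
  expect_false(any(tr0$bound))

  static <- simulate_tracks(sc, 10, fraction_bound = 0, D_free = 0,
                            n_frames = 15, seed = 2)
  for (id in unique(static$track_id)) {
    s <- static[static$track_id == id, ]
    expect_equal(var(s$x), 0)
    expect_equal(var(s$y), 0)
  }
  expect_error(simulate_tracks(sc, 5, 0.5, dt = 0, seed = 1),
               class = "evcoloc_validation_error")
  expect_error(simulate_tracks(sc, 5, 1.5, seed = 1),
               class = "evcoloc_validation_error")
})

test_that("free-particle MSD matches the Brownian closed form within 10%", {
  big <- filament_scene(0, field = c(51200, 51200), seed = 1)
  D <- 0.2; dt <- 0.03
  tr <- simulate_tracks(big, 500, fraction_bound = 0, D_free = D,
                        n_frames = 30, dt = dt, seed = 3)
  sq <- unlist(lapply(split(tr, tr$track_id), function(s) {
    diff(s$x)^2 + diff(s$y)^2
  }))
  expect_lt(abs(mean(sq) / (4 * D * 1e6 * dt) - 1), 0.10)
})

test_that("bound particles stay within the 50-nm boundary band at every frame", {
  sc <- small_scene()
  tr <- simulate_tracks(sc, 40, fraction_bound = 1, n_frames = 40, seed = 5)
  d <- scene_signed_distance(sc, cbind(tr$x, tr$y))
  expect_true(all(abs(d) <= 50 + 1e-9))
})

test_that("spot rendering conserves flux and places peaks correctly", {
  # zero points, zero noise -> constant background
  stk <- render_spot_stack(list(NULL, NULL), dim = c(16, 16), psf_sigma = 150,
                           pixel = 100, noise = c(0, 7), seed = 1)
  expect_true(all(stk$images[[1]] == 7))

  # one emitter at the center of pixel (8, 8) -> stack argmax there
  one <- render_spot_stack(list(cbind(750, 750)), dim = c(16, 16),
                           psf_sigma = 130, pixel = 100, noise = c(0, 0),
                           seed = 1)
  peak <- which(one$images[[1]] == max(one$images[[1]]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(8, 8))

  # flux conservation within 1%
  pts <- uniform_points(c(4000, 4000), 25, seed = 4) + 6000
  flux <- render_spot_stack(list(pts), dim = c(160, 160), psf_sigma = 150,
                            pixel = 100, intensity = 1000,
                            noise = c(0, 3), seed = 1)
  total <- sum(flux$images[[1]]) - 3 * 160 * 160
  expect_lt(abs(total / (25 * 1000) - 1), 0.01)

  # out-of-field points clipped with a warning, tallied in truth
  expect_warning(
    clipped <- render_spot_stack(list(cbind(c(500, -50), c(500, 500))),
                                 dim = c(10, 10), psf_sigma = 100,
                                 pixel = 100, seed = 1),
    "clipped")
  expect_equal(attr(clipped, "truth")$n_clipped, 1L)
})

test_that("uniform point placement is uniform, seeded and region-aware", {
  expect_equal(nrow(uniform_points(c(1000, 2000), 0, seed = 1)), 0)
  expect_identical(uniform_points(c(1000, 2000), 50, seed = 9),
                   uniform_points(c(1000, 2000), 50, seed = 9))

  # rectangle: empirical mean within 3 SE of the center at n = 10,000
  p <- uniform_points(c(1000, 2000), 10000, seed = 2)
  se_x <- 1000 / sqrt(12) / sqrt(10000)
  se_y <- 2000 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(p[, 1]) - 500), 3 * se_x)
  expect_lt(abs(mean(p[, 2]) - 1000), 3 * se_y)

  # mask region: every point's containing pixel is in-mask
  m <- matrix(0L, 20, 20); m[5:10, 12:17] <- 1L
  mask <- evcoloc:::new_binary_mask(m, pixel = 10)
  q <- uniform_points(mask, 500, seed = 3)
  rr <- floor(q[, 2] / 10) + 1
  cc <- floor(q[, 1] / 10) + 1
  expect_true(all(m[cbind(rr, cc)] == 1L))

  empty <- evcoloc:::new_binary_mask(matrix(0L, 5, 5), pixel = 10)
  expect_error(uniform_points(empty, 5, seed = 1),
               class = "evcoloc_validation_error")
})
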