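test_that("window enumeration reproduces the published scheme", {
  sch <- window_scheme(T = 3504, W = 1002, S = 6)
  starts <- window_starts(sch)
  expect_length(starts, 417)
  expect_equal(starts[1], 1)
  expect_equal(starts[1] + sch$W - 1, 1002)
  expect_equal(diff(starts), rep(6, 416))

  expect_length(window_starts(window_scheme(2004, 1002, 6)), 167)
  s1 <- window_starts(window_scheme(1008, 1002, 6))
  expect_equal(s1, 1L)
  expect_error(window_scheme(1000, 1002, 6), class = "evcoloc_validation_error")
})

test_that("uncertainty filtering matches direct enumeration", {
  tab <- loc_table(data.frame(frame = 1:100, x = runif(100), y = runif(100),
                              uncertainty = runif(100, 0.5, 150)))
  all_kept <- filter_uncertainty(tab, 0, Inf)
  expect_equal(nrow(all_kept$records), nrow(tab$records))

  none <- filter_uncertainty(tab, 200, 300)
  expect_equal(nrow(none$records), 0)
  expect_equal(attr(none, "filter")$n_rejected, nrow(tab$records))

  f <- filter_uncertainty(tab, 10, 80)
  brute <- sum(tab$records$uncertainty >= 10 & tab$records$uncertainty <= 80)
  expect_equal(nrow(f$records), brute)
})

test_that("a single kernel has the documented SD, peak and unit mass", {
  # one localization at the center of pixel (col 50, row 50), u = 4 nm, A = 6
  tab <- loc_table(data.frame(frame = 1, x = 495, y = 495, uncertainty = 4))
  pm <- probability_map(tab, render_params(), field = c(1000, 1000))
  expect_equal(unname(which(pm$values == max(pm$values), arr.ind = TRUE)[1, ]),
               c(50, 50))
  mass <- sum(pm$values) * pm$pixel^2
  expect_gte(mass, 0.999)
  expect_lte(mass, 1.0)
  # kernel SD = A * u = 24 nm: value one pixel off matches the Gaussian
  expect_equal(pm$values[50, 51] / pm$values[50, 50],
               dnorm(10, 0, 24) / dnorm(0, 0, 24), tolerance = 1e-9)
})

test_that("the map is invariant to duplication and record order", {
  rec <- data.frame(frame = 1, x = runif(40, 200, 800),
                    y = runif(40, 200, 800),
                    uncertainty = runif(40, 5, 20))
  p1 <- probability_map(loc_table(rec), render_params(), c(1000, 1000))
  p2 <- probability_map(loc_table(rbind(rec, rec)), render_params(),
                        c(1000, 1000))
  expect_equal(p2$values, p1$values, tolerance = 1e-12)
  p3 <- probability_map(loc_table(rec[sample.int(40), ]), render_params(),
                        c(1000, 1000))
  expect_equal(p3$values, p1$values, tolerance = 1e-12)
})

test_that("the rendered map equals the naive per-pixel oracle", {
  set.seed(42)
  rec <- data.frame(frame = 1, x = runif(60, 0, 1200),
                    y = runif(60, 0, 1200),
                    uncertainty = runif(60, 3, 30))
  pm <- probability_map(loc_table(rec), render_params(), c(1200, 1200))
  oracle <- naive_probability_map(rec, pixel = 10, A = 6, trunc = 4,
                                  nr = 120, nc = 120)
  expect_lt(max(abs(pm$values - oracle)) / max(oracle), 1e-9)
})

test_that("translation by whole pixels shifts the map identically", {
  rec <- data.frame(frame = 1, x = runif(30, 300, 600),
                    y = runif(30, 300, 600),
                    uncertainty = runif(30, 4, 15))
  base <- probability_map(loc_table(rec), render_params(), c(1200, 1200))
  shifted <- rec
  shifted$x <- shifted$x + 30   # 3 pixels right
  shifted$y <- shifted$y + 50   # 5 pixels down
  sh <- probability_map(loc_table(shifted), render_params(), c(1200, 1200))
  expect_equal(sh$values[6:120, 4:120], base$values[1:115, 1:117],
               tolerance = 1e-12)
})

test_that("map mass stays near 1 for interior spots regardless of N", {
  for (n in c(1, 10, 200)) {
    rec <- data.frame(frame = 1, x = runif(n, 500, 1500),
                      y = runif(n, 500, 1500),
                      uncertainty = runif(n, 4, 15))
    pm <- probability_map(loc_table(rec), render_params(), c(2000, 2000))
    expect_lt(abs(sum(pm$values) * 100 - 1), 1e-3)
  }
})

test_that("background mixing and the N = 0 case behave as specified", {
  empty <- loc_table()
  bg <- background_model(alpha = 0.8, mu_bg = 2e-6)
  pm <- probability_map(empty, render_params(background = bg), c(500, 500))
  expect_true(all(abs(pm$values - 0.2 * 2e-6) < 1e-18))

  # sampled mode is seeded and reproducible
  bgs <- background_model(alpha = 0, mu_bg = 1e-6, sigma_bg = 1e-7,
                          mode = "sampled", seed = 4)
  p1 <- probability_map(empty, render_params(background = bgs), c(300, 300))
  p2 <- probability_map(empty, render_params(background = bgs), c(300, 300))
  expect_identical(p1$values, p2$values)
  expect_gt(sd(p1$values), 0)
})

test_that("movie windows slice the table correctly", {
  sc <- small_scene()
  tab <- sample_localizations(sc, blink_model(per_frame_density = 0.08),
                              n_frames = 330, seed = 6)
  scheme <- window_scheme(T = 330, W = 300, S = 6)
  movie <- build_movie(tab, scheme, render_params(), field = sc$field)
  expect_length(movie, 5)

  # single-window scheme
  one <- build_movie(tab, window_scheme(T = 306, W = 300, S = 6),
                     render_params(), field = sc$field)
  expect_length(one, 1)

  # empty table, alpha = 1 -> all-zero maps
  zero <- build_movie(loc_table(), window_scheme(306, 300, 6),
                      render_params(), field = c(1000, 1000))
  expect_true(all(zero[[1]]$values == 0))

  # consecutive windows differ exactly by the exchanged frames' kernels
  r <- filter_uncertainty(tab, 2, 100)$records
  params <- render_params()
  for (k in 1:2) {
    s <- window_starts(scheme)[k]
    lost <- r[r$frame >= s & r$frame < s + 6, ]
    gained <- r[r$frame >= s + 300 & r$frame < s + 306, ]
    n_k <- sum(r$frame >= s & r$frame <= s + 299)
    n_k1 <- n_k - nrow(lost) + nrow(gained)
    splat <- function(rec) {
      if (nrow(rec) == 0) return(0)
      nrow(rec) * probability_map(loc_table(rec), params, sc$field)$values
    }
    delta <- splat(gained) - splat(lost)
    expect_equal(n_k1 * movie[[k + 1]]$values - n_k * movie[[k]]$values,
                 delta, tolerance = 1e-9)
  }
})

test_that("display rendering splats fixed 24-nm kernels", {
  empty <- render_display(loc_table(), field = c(500, 500))
  expect_true(all(empty$values == 0))

  one <- loc_table(data.frame(frame = 1, x = 245, y = 245, uncertainty = 30))
  img <- render_display(one, field = c(500, 500))
  expect_equal(unname(which(img$values == max(img$values), arr.ind = TRUE)[1, ]),
               c(25, 25))

  n <- 20
  many <- loc_table(data.frame(frame = 1, x = runif(n, 150, 850),
                               y = runif(n, 150, 850),
                               uncertainty = runif(n, 5, 50)))
  img2 <- render_display(many, field = c(1000, 1000))
  expect_lt(abs(sum(img2$values) - n), n * 1e-3)
})

test_that("window-to-particle-frame synchronization is exact and monotone", {
  sch <- window_scheme(3504, 1002, 6)
  expect_error(sync_index(sch, avg_block = 10),
               class = "evcoloc_validation_error")
  idx <- sync_index(sch, avg_block = 6)
  expect_length(idx, 417)
  # first window (frames 1-1002, middle 501.5) pairs with the averaged
  # frame centered at original frame 501.5: block 84 covers frames 499-504
  expect_equal(idx[1], 84L)
  expect_equal(idx[1] * 6 - 2.5, 501.5)
  expect_true(all(diff(idx) == 1L))
})
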