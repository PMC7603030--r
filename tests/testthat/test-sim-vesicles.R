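test_that("frame count follows duration / interval", {
  p <- vesicle_movie_params(frame_interval_s = 0.2, duration_s = 120)
  expect_identical(p$n_frames, 600L)
  p2 <- vesicle_movie_params(frame_interval_s = 0.5, duration_s = 10)
  expect_identical(p2$n_frames, 20L)
  expect_identical(vesicle_movie_params(n_frames = 7)$n_frames, 7L)
})

test_that("planted directed tracks move at the requested step length", {
  p <- vesicle_movie_params(n_frames = 40, n_vesicles = 8,
                            speed_px_per_frame = 1.5, motion = "directed",
                            seed = 6)
  sim <- generate_vesicle_movie(p)
  tk <- sim$truth$tracks_true
  for (id in unique(tk$track_id)) {
    t1 <- tk[tk$track_id == id, ]
    steps <- sqrt(diff(t1$x)^2 + diff(t1$y)^2)
    expect_equal(steps, rep(1.5, 39), tolerance = 1e-9)
  }
})

test_that("brownian steps have the same length but shorter displacement", {
  mk <- function(motion) {
    p <- vesicle_movie_params(n_frames = 60, n_vesicles = 10,
                              speed_px_per_frame = 2, motion = motion,
                              seed = 17)
    generate_vesicle_movie(p)$truth$tracks_true
  }
  disp <- function(tk) {
    mean(vapply(split(tk, tk$track_id), function(t1)
      sqrt((t1$x[60] - t1$x[1])^2 + (t1$y[60] - t1$y[1])^2), 0))
  }
  td <- mk("directed"); tb <- mk("brownian")
  sb <- sqrt(diff(tb$x[tb$track_id == 1])^2 +
               diff(tb$y[tb$track_id == 1])^2)
  expect_equal(sb, rep(2, 59), tolerance = 1e-9)
  expect_gt(disp(td), disp(tb))
})

test_that("stationary tracks do not move; positions stay in bounds", {
  p <- vesicle_movie_params(n_frames = 30, n_vesicles = 6,
                            speed_px_per_frame = 3, motion = "stationary",
                            seed = 2)
  tk <- generate_vesicle_movie(p)$truth$tracks_true
  expect_true(all(tapply(tk$x, tk$track_id,
                         function(v) diff(range(v))) == 0))
  expect_true(all(tapply(tk$y, tk$track_id,
                         function(v) diff(range(v))) == 0))
  p2 <- vesicle_movie_params(n_frames = 200, n_vesicles = 10,
                             speed_px_per_frame = 4, seed = 3)
  tk2 <- generate_vesicle_movie(p2)$truth$tracks_true
  expect_true(all(tk2$x >= 0 & tk2$x <= 127 & tk2$y >= 0 & tk2$y <= 127))
})

test_that("spots have roughly the configured above-half-max area", {
  p <- vesicle_movie_params(n_frames = 1, n_vesicles = 1,
                            vesicle_area_px = 12, spot_peak = 200,
                            background_level = 0, seed = 5)
  fr <- get_frame(generate_vesicle_movie(p)$stack, 1)
  expect_equal(sum(fr > 100), 12, tolerance = 0.35)
})

test_that("bleaching dims whole frames by exp(-k (t-1))", {
  # compare with the unbleached twin (same seed, same tracks): bleaching
  # must be a pure per-frame scalar. Frame means alone are not exactly
  # exponential because moving spots lose varying Gaussian tail mass off
  # the image border.
  p0 <- vesicle_movie_params(n_frames = 50, n_vesicles = 5, seed = 4)
  pb <- vesicle_movie_params(n_frames = 50, n_vesicles = 5,
                             bleach_rate_per_frame = 0.02, seed = 4)
  a0 <- generate_vesicle_movie(p0)$stack$data
  ab <- generate_vesicle_movie(pb)$stack$data
  for (t in c(1, 10, 50))
    expect_equal(ab[t, 1, , ], a0[t, 1, , ] * exp(-0.02 * (t - 1)),
                 tolerance = 1e-12)
})

test_that("movies are reproducible by seed", {
  p <- vesicle_movie_params(n_frames = 10, noise_model = "poisson",
                            seed = 12)
  a <- generate_vesicle_movie(p)
  b <- generate_vesicle_movie(p)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$tracks_true, b$truth$tracks_true)
})
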