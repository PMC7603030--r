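gauss_spot <- function(shape, cy, cx, peak = 150, sigma = 1.66) {
  y <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1], shape[2])
  x <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  peak * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
}

test_that("detection filters by component area (5-30 px window)", {
  img <- matrix(0, 64, 64)
  img[10:10, 10:12] <- 100          # 3 px: too small
  img[30:33, 30:33] <- 100          # 16 px: keep
  img[50:58, 50:54] <- 100          # 45 px: too large
  det <- detect_vesicles(img, min_area_px = 5, max_area_px = 30)
  expect_equal(nrow(det), 1)
  expect_equal(det$area_px, 16L)
  expect_equal(det$x, 30.5, tolerance = 1e-9)   # 0-based centroid
  expect_equal(det$y, 30.5, tolerance = 1e-9)
})

test_that("centroids are intensity-weighted and sub-pixel accurate", {
  img <- matrix(0, 40, 40) + gauss_spot(c(40, 40), 20.3, 17.7)
  det <- detect_vesicles(img)
  expect_equal(det$y, 20.3, tolerance = 0.05)
  expect_equal(det$x, 17.7, tolerance = 0.05)
})

test_that("a straight-line track is recovered with exact statistics", {
  dets <- data.frame(frame = 1:10, x = 1.5 * (0:9), y = rep(5, 10))
  tk <- link_tracks(dets)
  expect_equal(length(unique(tk$track_id)), 1)
  st <- track_stats(tk)
  expect_equal(st$mean_speed, 1.5)
  expect_equal(st$displacement, 13.5)
  expect_equal(st$path_length, 13.5)
})

test_that("links beyond max_link_px start a new track", {
  dets <- data.frame(frame = c(1, 2), x = c(0, 10), y = c(0, 0))
  tk <- link_tracks(dets, max_link_px = 5)
  expect_equal(length(unique(tk$track_id)), 2)
  tk2 <- link_tracks(dets, max_link_px = 11)
  expect_equal(length(unique(tk2$track_id)), 1)
})

test_that("gap closing bridges a single missed frame", {
  dets <- data.frame(frame = c(1, 2, 4, 5), x = c(0, 1, 3, 4),
                     y = rep(0, 4))
  tk <- link_tracks(dets, max_link_px = 3, max_gap_frames = 1)
  expect_equal(length(unique(tk$track_id)), 1)
  tk0 <- link_tracks(dets, max_link_px = 3, max_gap_frames = 0)
  expect_equal(length(unique(tk0$track_id)), 2)
})

test_that("crossing detections link to their nearest predecessors", {
  # two tracks approaching; greedy global-minimum keeps each with its own
  dets <- rbind(data.frame(frame = 1, x = c(0, 10), y = c(0, 0)),
                data.frame(frame = 2, x = c(1, 9), y = c(0, 0)))
  tk <- link_tracks(dets, max_link_px = 10)
  expect_equal(length(unique(tk$track_id)), 2)
  a <- tk[tk$track_id == tk$track_id[tk$frame == 1 & tk$x == 0], ]
  expect_equal(sort(a$x), c(0, 1))
})

test_that("empty detections give an empty track table and NA summary", {
  tk <- link_tracks(NULL)
  expect_equal(nrow(tk), 0)
  s <- summarize_motility(tk)
  expect_identical(s$n_tracks, 0L)
  expect_true(is.na(s$mean_speed))
  expect_true(is.na(s$mean_displacement))
})

test_that("summaries convert to physical units when calibrated", {
  dets <- data.frame(frame = 1:10, x = 2 * (0:9), y = rep(0, 10))
  tk <- link_tracks(dets)
  px <- summarize_motility(tk)
  expect_identical(px$units, "px_per_frame")
  expect_equal(px$mean_speed, 2)
  um <- summarize_motility(tk, pixel_size_um = 0.1, frame_interval_s = 0.2)
  expect_identical(um$units, "um_per_s")
  expect_equal(um$mean_speed, 2 * 0.1 / 0.2)
  expect_equal(um$mean_displacement, 18 * 0.1)
})

test_that("full pipeline recovers a planted speed end to end", {
  p <- vesicle_movie_params(n_frames = 80, n_vesicles = 12,
                            speed_px_per_frame = 1, motion = "directed",
                            noise_model = "none", seed = 19)
  res <- analyze_vesicle_movie(generate_vesicle_movie(p)$stack)
  got <- speed_in_px_per_frame(res$summary, p$pixel_size_um,
                               p$frame_interval_s)
  expect_equal(got, 1, tolerance = 0.05)
})

test_that("min_track_len excludes short tracks from the summary", {
  dets <- rbind(data.frame(frame = 1:10, x = 0:9, y = 0),
                data.frame(frame = 1:3, x = 20:22, y = 20))
  tk <- link_tracks(dets)
  s <- summarize_motility(tk, min_track_len = 5)
  expect_identical(s$n_tracks, 1L)
})
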