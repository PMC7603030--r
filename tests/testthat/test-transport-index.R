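# An 8x8 two-channel toy where every quantity is known by hand:
# marker = bright 2x2 block (Golgi), cargo has 40 counts inside it and 10
# outside, so raw = 40/10 = 4 at t1 and (normalized) TI doubles when the
# inside mass doubles.
toy_stacks <- function() {
  marker <- matrix(0, 8, 8)
  marker[3:4, 3:4] <- 100
  cargo1 <- matrix(0, 8, 8)
  cargo1[3:4, 3:4] <- 10            # 4 px * 10 = 40 inside
  cargo1[7:8, 7:8] <- 2.5           # 4 px * 2.5 = 10 outside
  cargo2 <- cargo1
  cargo2[3:4, 3:4] <- 20            # inside mass doubles
  list(cargo = stack_from_frames(list(cargo1, cargo2),
                                 timepoints_min = c(0, 10)),
       marker = stack_from_frames(list(marker, marker),
                                  timepoints_min = c(0, 10)))
}

test_that("toy raw ratio and normalization are exact", {
  s <- toy_stacks()
  roi <- cell_roi(1, matrix(TRUE, 8, 8))
  ti <- compute_transport_index(s$cargo, s$marker, roi, "soluble",
                                cargo_background_radius = NA,
                                marker_background_radius = 3,
                                erode_iterations = 0L)
  expect_equal(ti$raw_ratio, c(4, 8))
  expect_equal(ti$ti, c(1, 2))
  expect_equal(ti$time_min, c(0, 10))
})

test_that("TI at the initiation timepoint is exactly 1", {
  sim <- generate_transport_series(scene_params(seed = 3),
                                   kinetics_preset("high", "soluble"))
  ch <- split_channels(sim$stack)
  roi <- cell_roi(1, sim$truth$cell_masks_true == 1, "ground_truth")
  ti <- compute_transport_index(ch$cargo, ch$golgi_marker, roi, "soluble")
  expect_identical(ti$ti[1], 1)
})

test_that("TI is invariant to rescaling the cargo channel", {
  s <- toy_stacks()
  roi <- cell_roi(1, matrix(TRUE, 8, 8))
  args <- list(marker_stack = s$marker, roi = roi, cargo_type = "soluble",
               cargo_background_radius = NA, marker_background_radius = 3,
               erode_iterations = 0L)
  t1 <- do.call(compute_transport_index, c(list(s$cargo), args))
  s2 <- s$cargo; s2$data <- s2$data * 3.7
  t2 <- do.call(compute_transport_index, c(list(s2), args))
  expect_equal(t1$ti, t2$ti)
})

test_that("golgi mask recipe matches Otsu + two erosions done by hand", {
  sim <- generate_transport_series(scene_params(seed = 3),
                                   kinetics_preset("none", "soluble"))
  marker <- get_frame(sim$stack, 1, "golgi_marker")
  roi <- cell_roi(1, sim$truth$cell_masks_true == 1, "ground_truth")
  got <- compute_golgi_mask(marker, roi)
  bg <- rolling_ball_background_subtract(marker, 50)
  thr <- otsu_threshold(matrix(bg[roi$mask], ncol = 1))$threshold
  manual <- erode_binary((bg > thr) & roi$mask, 2)
  expect_identical(got, manual)
})

test_that("background-referenced sums correct the noise pedestal", {
  scene <- scene_params(seed = 15, noise_model = "poisson")
  kin <- kinetics_preset("very_high", "soluble")
  sim <- generate_transport_series(scene, kin)
  ch <- split_channels(sim$stack)
  roi <- cell_roi(1, sim$truth$cell_masks_true == 1, "ground_truth")
  plain <- compute_transport_index(ch$cargo, ch$golgi_marker, roi,
                                   "soluble")
  refd <- compute_transport_index(ch$cargo, ch$golgi_marker, roi,
                                  "soluble",
                                  background_mask = background_region(roi))
  truth <- sim$truth$predicted_ti
  # referencing must reduce the end-point error substantially
  expect_lt(abs(refd$ti[5] - truth[5]), abs(plain$ti[5] - truth[5]))
  expect_lt(abs(refd$ti[5] - truth[5]) / truth[5], 0.1)
})

test_that("background mask is validated", {
  s <- toy_stacks()
  roi <- cell_roi(1, matrix(TRUE, 8, 8))
  expect_error(
    compute_transport_index(s$cargo, s$marker, roi, "soluble",
                            background_mask = matrix(TRUE, 8, 8)),
    class = "secrflux_input_error")  # overlaps the ROI
  expect_error(
    compute_transport_index(s$cargo, s$marker, roi, "soluble",
                            background_mask = matrix(FALSE, 4, 4)),
    class = "secrflux_input_error")  # wrong shape
})

test_that("classification thresholds are half-open toward the top class", {
  mk <- function(ti30, type = "soluble") {
    tmin <- if (type == "soluble") c(0, 30) else c(0, 15)
    structure(data.frame(time_min = tmin, raw_ratio = c(1, ti30),
                         ti = c(1, ti30)),
              class = c("ti_trajectory", "data.frame"),
              cargo_type = type, cell_label = 1L)
  }
  expect_equal(classify_transport(mk(10))$label, "very_high")
  expect_equal(classify_transport(mk(9.999))$label, "high")
  expect_equal(classify_transport(mk(5))$label, "high")
  expect_equal(classify_transport(mk(2))$label, "moderate")
  expect_equal(classify_transport(mk(1.999))$label, "none")
  expect_equal(classify_transport(mk(7, "transmembrane"))$label, "high")
  expect_equal(classify_transport(mk(6.999, "transmembrane"))$label,
               "moderate")
  expect_equal(classify_transport(mk(4, "transmembrane"))$label,
               "moderate")
  expect_equal(classify_transport(mk(3.999, "transmembrane"))$label,
               "none")
})

test_that("classification requires the decision timepoint", {
  bad <- structure(data.frame(time_min = c(0, 10), raw_ratio = c(1, 2),
                              ti = c(1, 2)),
                   class = c("ti_trajectory", "data.frame"),
                   cargo_type = "soluble")
  expect_error(classify_transport(bad), class = "secrflux_input_error")
})

test_that("population summary aggregates mean, SEM and class counts", {
  mk <- function(ti30) {
    structure(data.frame(time_min = c(0, 30), raw_ratio = c(1, ti30),
                         ti = c(1, ti30)),
              class = c("ti_trajectory", "data.frame"),
              cargo_type = "soluble", cell_label = 1L)
  }
  s <- summarize_population(list(mk(6), mk(8), mk(1.5)), "ctrl")
  expect_equal(s$timecourse$mean_ti, c(1, mean(c(6, 8, 1.5))))
  expect_equal(s$timecourse$sem_ti[2], sd(c(6, 8, 1.5)) / sqrt(3))
  cf <- s$class_freq
  expect_equal(cf$count[cf$class == "high"], 2L)
  expect_equal(cf$count[cf$class == "none"], 1L)
  expect_equal(sum(cf$pct), 100)
  # single-cell SEM is 0, not NA
  s1 <- summarize_population(list(mk(6)))
  expect_equal(s1$timecourse$sem_ti, c(0, 0))
})

test_that("chi-square comparison runs on two populations", {
  mk <- function(ti30) {
    structure(data.frame(time_min = c(0, 30), raw_ratio = c(1, ti30),
                         ti = c(1, ti30)),
              class = c("ti_trajectory", "data.frame"),
              cargo_type = "soluble", cell_label = 1L)
  }
  a <- summarize_population(lapply(c(6, 7, 8, 6.5), mk))
  b <- summarize_population(lapply(c(1.2, 1.1, 2.5, 1.3), mk))
  ht <- suppressWarnings(compare_class_frequencies(a, b))
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 1)
})
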