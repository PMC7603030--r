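test_that("Crofton perimeter of rasterized discs approaches 2*pi*r", {
  for (r in c(10, 20, 40)) {
    p <- perimeter_crofton(disc_mask(r))
    expect_equal(p, 2 * pi * r, tolerance = 0.04)
  }
})

test_that("form factor of a disc is near 1 and rises with radius", {
  ffs <- vapply(c(20, 40, 60), function(r) form_factor(disc_mask(r)), 0)
  expect_true(all(ffs >= 0.85))
  expect_true(all(diff(ffs) > 0))
  expect_true(all(ffs <= 1))
})

test_that("form factor decreases with elongation", {
  mk_rect <- function(h, w) {
    m <- matrix(FALSE, h + 10, w + 10)
    m[6:(5 + h), 6:(5 + w)] <- TRUE
    m
  }
  ffs <- c(form_factor(mk_rect(10, 10)), form_factor(mk_rect(5, 20)),
           form_factor(mk_rect(2, 50)))
  expect_true(all(diff(ffs) < 0))
})

test_that("20x2 rectangle matches the closed form within estimator bias", {
  m <- matrix(FALSE, 12, 30)
  m[6:7, 6:25] <- TRUE
  closed <- 4 * pi * 40 / 44^2            # area 40, perimeter 44
  got <- form_factor(m)
  # Crofton underestimates straight axis-aligned edges; documented ~20%
  expect_equal(got, closed, tolerance = 0.20)
})

test_that("empty and degenerate masks raise errors", {
  expect_error(form_factor(matrix(FALSE, 5, 5)),
               class = "secrflux_input_error")
  expect_error(mask_iou(matrix(2, 3, 3), matrix(TRUE, 3, 3)),
               class = "secrflux_input_error")
})

test_that("mask IoU has its defining properties", {
  a <- disc_mask(10)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, !a), 0)
  b <- a
  b[1:3, ] <- FALSE
  iou <- mask_iou(a, b)
  expect_equal(iou, sum(b) / sum(a))
  expect_true(is.na(mask_iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4))))
})

test_that("blanking the Golgi region makes form factors marker-invariant", {
  scene <- scene_params(seed = 23)
  sim <- generate_transport_series(scene, kinetics_preset("high",
                                                          "soluble"))
  ch <- split_channels(sim$stack)
  roi <- cell_roi(1, sim$truth$cell_masks_true == 1, "ground_truth")
  cargo <- get_frame(ch$cargo, 2)
  marker <- get_frame(ch$golgi_marker, 2)
  base <- compute_form_factors(cargo, marker, roi, time_min = 3)
  # quadruple the cargo intensity inside the true Golgi footprint: the
  # record must not change, because that region is blanked before any
  # neighbourhood operation
  cargo2 <- cargo
  gm <- sim$truth$golgi_mask_true == 1
  inner <- erode_binary(gm, 4)     # strictly inside the derived mask
  cargo2[inner] <- cargo2[inner] * 4
  pert <- compute_form_factors(cargo2, marker, roi, time_min = 3)
  expect_equal(pert$median_form_factor, base$median_form_factor)
  expect_equal(pert$n_structures, base$n_structures)
})

test_that("a cell with no structures yields a flagged record, not an error", {
  cargo <- matrix(10, 96, 96)      # featureless
  marker <- matrix(10, 96, 96)
  marker[40:56, 40:56] <- 500
  roi <- cell_roi(1, matrix(TRUE, 96, 96))
  rec <- compute_form_factors(cargo, marker, roi,
                              rolling_ball_radius = 30,
                              marker_background_radius = 30)
  expect_true(rec$empty)
  expect_identical(rec$n_structures, 0L)
  expect_true(is.na(rec$median_form_factor))
})

test_that("microtubule ratio responds to planted contrast", {
  scene <- scene_params(seed = 33)
  roi_of <- function(fl) cell_roi(1, fl$truth$cell_masks_true == 1,
                                  "ground_truth")
  lo <- generate_filament_image(scene, 10, contrast = 2)
  hi <- generate_filament_image(scene, 10, contrast = 5)
  r_lo <- compute_microtubule_ratio(get_frame(lo$stack, 1), roi_of(lo))
  r_hi <- compute_microtubule_ratio(get_frame(hi$stack, 1), roi_of(hi))
  expect_gt(r_hi$ratio, r_lo$ratio)
  expect_gt(r_lo$ratio, 1)
})

test_that("microtubule ratio is invariant to intensity rescaling", {
  scene <- scene_params(seed = 34)
  fl <- generate_filament_image(scene, 10, contrast = 3)
  roi <- cell_roi(1, fl$truth$cell_masks_true == 1, "ground_truth")
  img <- get_frame(fl$stack, 1)
  r1 <- compute_microtubule_ratio(img, roi)
  r2 <- compute_microtubule_ratio(img * 2.5, roi)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-6)
})

test_that("filament mask overlaps the planted filaments", {
  scene <- scene_params(seed = 35, noise_model = "poisson")
  fl <- generate_filament_image(scene, 12, contrast = 3)
  roi <- cell_roi(1, fl$truth$cell_masks_true == 1, "ground_truth")
  r <- compute_microtubule_ratio(get_frame(fl$stack, 1), roi)
  tm <- fl$truth$filament_mask_true
  recall <- sum(r$filament_mask & tm) / sum(tm)
  precision <- sum(r$filament_mask & tm) / sum(r$filament_mask)
  expect_gt(recall, 0.7)
  expect_gt(precision, 0.7)
})

test_that("degenerate filament images raise classed errors", {
  roi <- cell_roi(1, matrix(TRUE, 64, 64))
  expect_error(compute_microtubule_ratio(matrix(7, 64, 64), roi),
               class = "secrflux_degenerate_error")
})
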