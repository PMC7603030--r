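#' Cauchy-Crofton perimeter estimate of a binary structure
#'
#' Estimates the boundary length of a binary region from the number of
#' foreground/background transitions along four families of digital lines
#' (horizontal, vertical and both diagonals), the Cauchy-Crofton
#' stereological formula:
#' \deqn{P \approx \frac{\pi}{8}\left(n_h + n_v +
#'   \frac{n_{d1} + n_{d2}}{\sqrt 2}\right).}
#' The estimator is exact in expectation for smooth convex shapes (a disc
#' gives `2*pi*r`), and biased for shapes with long straight axis-aligned
#' edges: squares and thin rectangles come out up to about 10% short,
#' which inflates their circularity by up to about 20%. Pixel-count
#' boundary estimators have far larger bias in the other direction (a disc
#' would score circularity ~0.8), which is why this estimator is used.
#'
#' @param mask logical or 0/1 matrix containing one structure.
#' @return Perimeter estimate in pixel units.
#' @export
perimeter_crofton <- function(mask) {
  m <- check_binary_mask(mask) * 1L
  pad <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nh <- sum(abs(pad[, -1L] - pad[, -ncol(pad)]))
  nv <- sum(abs(pad[-1L, ] - pad[-nrow(pad), ]))
  nd1 <- sum(abs(pad[-1L, -1L] - pad[-nrow(pad), -ncol(pad)]))
  nd2 <- sum(abs(pad[-1L, -ncol(pad)] - pad[-nrow(pad), -1L]))
  (pi / 8) * (nh + nv + (nd1 + nd2) / sqrt(2))
}

#' Form factor (circularity) of a binary structure
#'
#' `4 * pi * area / perimeter^2`, the standard circularity: 1 for a
#' perfect disc, tending to 0 for elongated shapes. Perimeter comes from
#' [perimeter_crofton()]; values are clamped to the unit interval to
#' absorb the estimator's small positive bias on near-circular discrete
#' shapes.
#'
#' @param mask logical or 0/1 matrix containing one structure.
#' @return Scalar in `(0, 1]`.
#' @export
form_factor <- function(mask) {
  m <- check_binary_mask(mask)
  a <- sum(m)
  if (a == 0) stop_input("empty structure has no form factor")
  p <- perimeter_crofton(m)
  min(1, 4 * pi * a / p^2)
}

#' Median form factor of non-Golgi fluorescent structures in a cell
#'
#' Quantifies disaggregation of ER-located cargo puncta: the Golgi region
#' (from the marker channel) is removed from the cargo image, background
#' is subtracted, structures inside the ROI are segmented with a local
#' (sliding-window) Otsu threshold, and the median circularity of all
#' structures is reported per cell and timepoint. The Golgi region is
#' blanked *before* background subtraction, so nothing inside the Golgi
#' mask can influence the record.
#'
#' @param cargo_image numeric matrix, cargo (GFP) frame.
#' @param marker_image numeric matrix, Golgi marker (RFP) frame.
#' @param roi a [cell_roi()].
#' @param window_px local-Otsu window (odd; default 51).
#' @param time_min acquisition time echoed into the record.
#' @param min_structure_px discard structures smaller than this (default
#'   5 px, below which circularity is meaningless).
#' @param rolling_ball_radius background radius for the cargo image.
#' @param marker_background_radius,erode_iterations Golgi-mask parameters.
#' @return A `form_factor_record`: list with `cell_label`, `time_min`,
#'   `n_structures`, `median_form_factor` (`NA` when no structures were
#'   found — flagged via `empty = TRUE`, not an error), and
#'   `form_factors` (per-structure values).
#' @export
compute_form_factors <- function(cargo_image, marker_image, roi,
                                 window_px = 51L, time_min = NA_real_,
                                 min_structure_px = 5L,
                                 rolling_ball_radius = 50,
                                 marker_background_radius = 50,
                                 erode_iterations = 2L) {
  check_matrix_image(cargo_image, "cargo_image")
  stopifnot(inherits(roi, "cell_roi"))
  gmask <- compute_golgi_mask(marker_image, roi,
                              rolling_ball_radius =
                                marker_background_radius,
                              erode_iterations = erode_iterations)
  work <- cargo_image
  work[gmask] <- 0                      # Golgi region removed first
  work <- rolling_ball_background_subtract(work, rolling_ball_radius)
  work[!roi$mask] <- 0
  fg <- local_otsu_threshold(work, window_px) & roi$mask & !gmask
  lab <- EBImage::bwlabel(fg * 1)
  ff <- numeric(0)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_structure_px)
    ff <- vapply(keep, function(k) form_factor(lab == k), 0)
  }
  structure(list(cell_label = roi$label, time_min = time_min,
                 n_structures = length(ff),
                 median_form_factor = if (length(ff)) median(ff)
                                      else NA_real_,
                 empty = length(ff) == 0L, form_factors = ff),
            class = "form_factor_record")
}

#' @export
print.form_factor_record <- function(x, ...) {
  cat(sprintf(
    "<form_factor_record> cell %d, t = %s min: %d structure(s), median FF %s\n",
    x$cell_label, format(x$time_min), x$n_structures,
    format(x$median_form_factor, digits = 3)))
  invisible(x)
}

#' Microtubule-mask intensity ratio
#'
#' Builds a filament mask by background subtraction, median filtering, a
#' spatial bandpass, Otsu thresholding, binary opening and a particle-size
#' filter, then reports the ratio of mean intensities of the microtubule
#' region and the remaining cytosolic region, both measured on the
#' background-subtracted image. The ratio is invariant to rescaling the
#' whole image.
#'
#' @param image numeric matrix, the filament (e.g. GFP-tubulin) frame.
#' @param roi a [cell_roi()].
#' @param rolling_ball_radius background radius, px.
#' @param median_radius radius of the median filter, px.
#' @param small_px,large_px bandpass cutoffs ([bandpass_filter()]).
#' @param open_size disc size of the binary opening.
#' @param min_particle_px discard mask particles smaller than this.
#' @return A `filament_ratio`: list with `position_label`,
#'   `mt_mean_intensity`, `cytosol_mean_intensity`, `ratio`, and
#'   `filament_mask`. An empty filament mask raises a degenerate-mask
#'   error.
#' @export
compute_microtubule_ratio <- function(image, roi,
                                      rolling_ball_radius = 50,
                                      median_radius = 1L, small_px = 3,
                                      large_px = 40, open_size = 3L,
                                      min_particle_px = 20L) {
  check_matrix_image(image)
  stopifnot(inherits(roi, "cell_roi"))
  if (length(unique(image[roi$mask])) < 2L)
    stop_degenerate("image constant within ROI")
  bg <- rolling_ball_background_subtract(image, rolling_ball_radius)
  mx <- max(bg)
  med <- if (mx > 0)
    EBImage::medianFilter(bg / mx, as.integer(median_radius)) * mx
  else bg
  band <- bandpass_filter(med, small_px, large_px)
  vals <- band[roi$mask]
  if (length(unique(vals)) < 2L)
    stop_degenerate("filtered image constant within ROI")
  thr <- otsu_threshold(matrix(vals, ncol = 1))$threshold
  mask <- (band > thr) & roi$mask
  mask <- open_binary(mask, open_size)
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_particle_px)
    mask[matrix(lab %in% small, nrow(lab), ncol(lab))] <- FALSE
  }
  if (!any(mask))
    stop_degenerate("filament mask empty after opening/size filter")
  cytosol <- roi$mask & !mask
  if (!any(cytosol))
    stop_degenerate("cytosolic region empty")
  mt_mean <- mean(bg[mask])
  cy_mean <- mean(bg[cytosol])
  structure(list(position_label = roi$label, mt_mean_intensity = mt_mean,
                 cytosol_mean_intensity = cy_mean,
                 ratio = mt_mean / cy_mean, filament_mask = mask),
            class = "filament_ratio")
}

#' @export
print.filament_ratio <- function(x, ...) {
  cat(sprintf(
    "<filament_ratio> position %d: MT mean %.4g / cytosol mean %.4g = %.3f\n",
    x$position_label, x$mt_mean_intensity, x$cytosol_mean_intensity,
    x$ratio))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical or 0/1 matrices of equal shape.
#' @return IoU in `[0, 1]` (`NA` when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  a <- check_binary_mask(a, "a"); b <- check_binary_mask(b, "b")
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
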