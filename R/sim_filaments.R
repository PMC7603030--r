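#' Generate a synthetic filament (microtubule-like) image
#'
#' Single frame with bright curvilinear structures laid over a dimmer
#' cytosolic field inside an elliptical cell. Filaments are smooth random
#' walks (slowly drifting heading) started near the cell centre and grown
#' until they hit the cell boundary; they are rendered as 1-px-radius
#' ridges at `(contrast - 1) * cytosol_level` above the cytosol, so pixels
#' on a filament carry `contrast` times the cytosolic intensity. The
#' ground-truth filament mask is the dilated path.
#'
#' @param scene a [scene_params()] (geometry, background, noise, seed).
#' @param n_filaments number of filaments (>= 0).
#' @param contrast on-filament / cytosol intensity ratio (> 1 for a
#'   detectable signal; default 3).
#' @param cytosol_level cytosolic intensity above background, counts.
#' @return A list with `stack` (single-frame [image_stack()]) and `truth`
#'   (`ground_truth` with `filament_mask_true` and `cell_masks_true`).
#' @export
generate_filament_image <- function(scene, n_filaments, contrast = 3,
                                    cytosol_level = 60) {
  stopifnot(inherits(scene, "scene_params"))
  if (n_filaments < 0) stop_param("n_filaments must be >= 0")
  shape <- scene$image_shape
  grid <- pixel_grid(shape)
  g <- scene_geometry(scene)[[1]]
  cell <- ellipse_mask(grid, g)

  path_mask <- matrix(FALSE, shape[1], shape[2])
  with_seed(scene$seed, {
    for (i in seq_len(n_filaments)) {
      # start near the centre, walk with slowly drifting heading
      y <- g$cy + runif(1, -0.3, 0.3) * g$ry
      x <- g$cx + runif(1, -0.3, 0.3) * g$rx
      th <- runif(1, 0, 2 * pi)
      for (dir in c(1, -1)) {     # grow both ways from the seed point
        yy <- y; xx <- x; hh <- th
        for (step in seq_len(600)) {
          yy <- yy + dir * sin(hh); xx <- xx + dir * cos(hh)
          hh <- hh + rnorm(1, 0, 0.07)
          r <- floor(yy) + 1; c <- floor(xx) + 1
          if (r < 1 || c < 1 || r > shape[1] || c > shape[2]) break
          if (!cell[r, c]) break
          path_mask[r, c] <- TRUE
        }
      }
    }
    fil_mask <- if (any(path_mask)) {
      EBImage::dilate(path_mask * 1, EBImage::makeBrush(3, "disc")) > 0.5
    } else path_mask
    img <- matrix(scene$background_level, shape[1], shape[2])
    img[cell] <- img[cell] + cytosol_level
    img[fil_mask & cell] <- img[fil_mask & cell] +
      (contrast - 1) * cytosol_level
    img <- apply_noise(img, scene)
  })

  stack <- image_stack(img, pixel_size_um = scene$pixel_size_um,
                       channel_names = "filaments")
  truth <- structure(list(
    filament_mask_true = fil_mask & cell,
    cell_masks_true = matrix(as.integer(cell), shape[1], shape[2]),
    contrast_true = contrast, seed = scene$seed
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Generate a synthetic ratiometric biosensor trace
#'
#' Piecewise trace with a stated basal plateau and endpoint level: the
#' ratio holds `basal_level` through the basal window, then moves linearly
#' to `end_level` at the final sample, with optional Gaussian noise.
#'
#' @param basal_level plateau ratio value.
#' @param end_level ratio value at the final sample.
#' @param n_points number of samples (>= 2).
#' @param noise_sd Gaussian noise s.d. added to every sample (>= 0).
#' @param seed integer seed for the noise.
#' @param time_step_s sampling interval in seconds.
#' @param basal_window_s `c(start, end)` of the basal window in seconds
#'   (clipped to at most 60% of the trace).
#' @return A [ratio_trace()] whose `"truth"` attribute records the planted
#'   basal and end levels.
#' @export
generate_ratio_trace <- function(basal_level, end_level, n_points,
                                 noise_sd = 0, seed = 1L, time_step_s = 10,
                                 basal_window_s = c(0, 300)) {
  if (n_points < 2L) stop_param("n_points must be >= 2")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  time_s <- (seq_len(n_points) - 1) * time_step_s
  span <- time_s[n_points]
  basal_end <- min(basal_window_s[2], 0.6 * span)
  ratio <- ifelse(time_s <= basal_end, basal_level,
                  basal_level + (end_level - basal_level) *
                    (time_s - basal_end) / (span - basal_end))
  if (noise_sd > 0)
    ratio <- with_seed(seed, ratio + rnorm(n_points, 0, noise_sd))
  ratio <- pmax(ratio, 1e-6)
  tr <- ratio_trace(time_s, ratio,
                    basal_window_s = c(basal_window_s[1], basal_end))
  attr(tr, "truth") <- list(basal_level = basal_level,
                            end_level = end_level, seed = seed)
  tr
}
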