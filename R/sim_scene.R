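#' Scene parameters for synthetic microscopy fields
#'
#' Describes the static geometry and camera model of a simulated field of
#' view: image size, physical calibration, number of cells (laid out on a
#' grid of tiles, one elliptical cell per tile), Golgi size, ER puncta
#' count, background offset and the noise model. Every generator call draws
#' all of its randomness from `seed`, so equal parameters give bit-identical
#' output; with `noise_model = "none"` the output is fully deterministic.
#'
#' @param image_shape integer vector `c(y, x)` in pixels.
#' @param pixel_size_um pixel size, micrometres per pixel (> 0).
#' @param cell_count number of cells (>= 1).
#' @param golgi_radius_px radius of the Golgi plateau disc, pixels.
#' @param puncta_count number of ER puncta per cell (>= 0).
#' @param background_level additive camera background, counts (>= 0).
#' @param noise_model `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param gaussian_sigma read-noise s.d. for `"poisson+gaussian"`, counts.
#' @param seed integer seed driving all randomness of a generator call.
#' @param marker_peak Golgi-marker plateau intensity, counts.
#' @param marker_edge_sigma_px Gaussian decay length of the marker disc
#'   edge. The default (1.72 px) places the half-intensity contour about
#'   2 px outside the plateau, so an Otsu mask followed by the standard two
#'   erosions lands on the true Golgi footprint.
#' @param golgi_clearance_px ER cargo is kept at least this far outside the
#'   Golgi disc, so Golgi and ER signal do not mix at the mask boundary.
#' @param cargo_core_margin_px Golgi-resident cargo occupies a disc this
#'   many pixels smaller than the marker disc, guaranteeing the eroded mask
#'   still captures all of it.
#' @param puncta_sigma_px base Gaussian radius of an ER punctum, pixels.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(192L, 192L), pixel_size_um = 0.1,
                         cell_count = 1L, golgi_radius_px = 24,
                         puncta_count = 30L, background_level = 20,
                         noise_model = c("none", "poisson",
                                         "poisson+gaussian"),
                         gaussian_sigma = 0, seed = 1L,
                         marker_peak = 1000, marker_edge_sigma_px = 1.72,
                         golgi_clearance_px = 3, cargo_core_margin_px = 4,
                         puncta_sigma_px = 2.2) {
  noise_model <- match.arg(noise_model)
  if (length(image_shape) != 2L || any(image_shape < 32))
    stop_param("image_shape must be c(y, x), each >= 32")
  if (pixel_size_um <= 0) stop_param("pixel_size_um must be > 0")
  if (cell_count < 1L) stop_param("cell_count must be >= 1")
  if (puncta_count < 0L) stop_param("puncta_count must be >= 0")
  if (background_level < 0) stop_param("background_level must be >= 0")
  if (gaussian_sigma < 0) stop_param("gaussian_sigma must be >= 0")
  p <- list(image_shape = as.integer(image_shape),
            pixel_size_um = pixel_size_um,
            cell_count = as.integer(cell_count),
            golgi_radius_px = golgi_radius_px,
            puncta_count = as.integer(puncta_count),
            background_level = background_level,
            noise_model = noise_model, gaussian_sigma = gaussian_sigma,
            seed = as.integer(seed), marker_peak = marker_peak,
            marker_edge_sigma_px = marker_edge_sigma_px,
            golgi_clearance_px = golgi_clearance_px,
            cargo_core_margin_px = cargo_core_margin_px,
            puncta_sigma_px = puncta_sigma_px)
  class(p) <- "scene_params"
  # geometry feasibility: the Golgi disc plus ER clearance must fit inside
  # each cell footprint
  geo <- scene_geometry(p)
  for (g in geo) {
    d_edge <- cell_boundary_distance(g)
    if (d_edge < golgi_radius_px + golgi_clearance_px + 2)
      stop_param("golgi_radius_px does not fit inside the cell footprint")
  }
  p
}

# per-cell geometry: tile layout, elliptical cell, offset Golgi centre
scene_geometry <- function(scene) {
  ny <- scene$image_shape[1]; nx <- scene$image_shape[2]
  n <- scene$cell_count
  rows <- ceiling(sqrt(n)); cols <- ceiling(n / rows)
  th <- ny / rows; tw <- nx / cols
  lapply(seq_len(n), function(i) {
    r <- (i - 1) %/% cols; c <- (i - 1) %% cols
    cy <- (r + 0.5) * th; cx <- (c + 0.5) * tw
    ry <- 0.42 * th; rx <- 0.42 * tw
    list(label = i, cy = cy, cx = cx, ry = ry, rx = rx,
         gy = cy + 0.15 * ry, gx = cx + 0.30 * rx)
  })
}

# distance from Golgi centre to the cell ellipse along the worst direction
cell_boundary_distance <- function(g) {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  by <- g$cy + g$ry * sin(th); bx <- g$cx + g$rx * cos(th)
  min(sqrt((by - g$gy)^2 + (bx - g$gx)^2))
}

# pixel-centre coordinate grids (0-based)
pixel_grid <- function(shape) {
  list(y = matrix(rep(0:(shape[1] - 1), shape[2]), shape[1], shape[2]),
       x = matrix(rep(0:(shape[2] - 1), each = shape[1]),
                  shape[1], shape[2]))
}

ellipse_mask <- function(grid, g) {
  ((grid$y - g$cy) / g$ry)^2 + ((grid$x - g$cx) / g$rx)^2 <= 1
}

apply_noise <- function(frame, scene) {
  if (scene$noise_model == "none") return(frame)
  out <- matrix(rpois(length(frame), lambda = as.vector(frame)),
                nrow(frame), ncol(frame))
  if (scene$noise_model == "poisson+gaussian" && scene$gaussian_sigma > 0) {
    out <- out + matrix(rnorm(length(frame), 0, scene$gaussian_sigma),
                        nrow(frame), ncol(frame))
    out[out < 0] <- 0
  }
  out
}
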