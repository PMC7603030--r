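#' Parameters of a synthetic vesicle movie
#'
#' High-frequency single-channel time lapse with compact moving spots. The
#' frame count follows the acquisition arithmetic
#' `round(duration_s / frame_interval_s)`; at the default 200 ms interval
#' over 2 min that is 600 frames. Tracks reflect off the image border so
#' planted displacements remain exact.
#'
#' @param n_frames number of frames; if `NULL` (default) computed from
#'   `duration_s` and `frame_interval_s`.
#' @param duration_s movie duration in seconds (default 120).
#' @param frame_interval_s frame interval in seconds (default 0.2).
#' @param image_shape `c(y, x)` pixels.
#' @param n_vesicles number of planted vesicles (>= 0).
#' @param speed_px_per_frame per-step distance, px/frame; scalar or one
#'   value per vesicle.
#' @param motion `"directed"` (fixed random heading), `"brownian"`
#'   (fresh random heading each frame, same step length), or
#'   `"stationary"`.
#' @param vesicle_area_px nominal spot area in pixels (area of the
#'   above-half-maximum region of the rendered Gaussian spot); default 12,
#'   inside the 5-30 px detection window.
#' @param spot_peak peak spot amplitude above background, counts.
#' @param background_level additive background, counts.
#' @param bleach_rate_per_frame exponential decay rate `k` of the
#'   frame-wide multiplicative bleaching factor `exp(-k * frame)` (>= 0).
#' @param noise_model `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param gaussian_sigma read-noise s.d., counts.
#' @param pixel_size_um pixel size, micrometres.
#' @param seed integer seed.
#' @return An object of class `vesicle_movie_params`.
#' @export
vesicle_movie_params <- function(n_frames = NULL, duration_s = 120,
                                 frame_interval_s = 0.2,
                                 image_shape = c(128L, 128L),
                                 n_vesicles = 20L,
                                 speed_px_per_frame = 1,
                                 motion = c("directed", "brownian",
                                            "stationary"),
                                 vesicle_area_px = 12,
                                 spot_peak = 150, background_level = 10,
                                 bleach_rate_per_frame = 0,
                                 noise_model = c("none", "poisson",
                                                 "poisson+gaussian"),
                                 gaussian_sigma = 0, pixel_size_um = 0.1,
                                 seed = 1L) {
  motion <- match.arg(motion)
  noise_model <- match.arg(noise_model)
  if (is.null(n_frames)) n_frames <- round(duration_s / frame_interval_s)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop_param("n_frames must be >= 1")
  if (frame_interval_s <= 0) stop_param("frame_interval_s must be > 0")
  if (n_vesicles < 0L) stop_param("n_vesicles must be >= 0")
  if (vesicle_area_px <= 0) stop_param("vesicle_area_px must be > 0")
  if (bleach_rate_per_frame < 0)
    stop_param("bleach_rate_per_frame must be >= 0")
  speed <- rep_len(speed_px_per_frame, max(n_vesicles, 1L))
  if (any(!is.finite(speed)) || any(speed < 0))
    stop_param("speed_px_per_frame must be finite and >= 0")
  structure(list(n_frames = n_frames, frame_interval_s = frame_interval_s,
                 image_shape = as.integer(image_shape),
                 n_vesicles = as.integer(n_vesicles),
                 speed_px_per_frame = speed[seq_len(n_vesicles)],
                 motion = motion, vesicle_area_px = vesicle_area_px,
                 spot_peak = spot_peak, background_level = background_level,
                 bleach_rate_per_frame = bleach_rate_per_frame,
                 noise_model = noise_model, gaussian_sigma = gaussian_sigma,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "vesicle_movie_params")
}

#' Generate a synthetic vesicle movie with known tracks
#'
#' Renders each vesicle as a Gaussian spot (sub-pixel centres recorded in
#' ground truth), moves it by the chosen motion model with reflecting
#' boundaries, applies the frame-wide bleaching factor
#' `exp(-k * (frame - 1))` and the scene noise model.
#'
#' @param params a [vesicle_movie_params()].
#' @return A list with `stack` (single-channel [image_stack()]) and `truth`
#'   (`ground_truth` with `tracks_true` — columns `track_id`, `frame`,
#'   `x`, `y`, 0-based pixel coordinates — `speed_true` and
#'   `bleach_rate_true`).
#' @export
generate_vesicle_movie <- function(params) {
  stopifnot(inherits(params, "vesicle_movie_params"))
  shape <- params$image_shape
  nt <- params$n_frames
  nv <- params$n_vesicles
  margin <- 4
  lo <- margin; hiy <- shape[1] - 1 - margin; hix <- shape[2] - 1 - margin
  sigma <- sqrt(params$vesicle_area_px / (2 * pi * log(2)))

  pos <- NULL
  arr <- array(0, c(nt, 1L, shape[1], shape[2]))
  tracks <- NULL
  with_seed(params$seed, {
    if (nv > 0) {
      py <- runif(nv, lo, hiy); px <- runif(nv, lo, hix)
      heading <- runif(nv, 0, 2 * pi)
      ty <- matrix(0, nt, nv); tx <- matrix(0, nt, nv)
      for (t in seq_len(nt)) {
        if (t > 1L && params$motion != "stationary") {
          if (params$motion == "brownian") heading <- runif(nv, 0, 2 * pi)
          # bounce off the border BEFORE moving: a heading that would
          # carry the centre outside is reflected and the full step is
          # retaken from the current position, so every step has the
          # exact planted length (folding the position instead would
          # shorten the chord between consecutive centres)
          for (i in seq_len(nv)) {
            s <- params$speed_px_per_frame[i]
            repeat {
              ny <- py[i] + s * sin(heading[i])
              nx <- px[i] + s * cos(heading[i])
              ok <- TRUE
              if (ny < lo || ny > hiy) { heading[i] <- -heading[i]
                                         ok <- FALSE }
              if (nx < lo || nx > hix) { heading[i] <- pi - heading[i]
                                         ok <- FALSE }
              if (ok) break
            }
            py[i] <- ny; px[i] <- nx
          }
        }
        ty[t, ] <- py; tx[t, ] <- px
      }
      tracks <- data.frame(
        track_id = rep(seq_len(nv), each = nt),
        frame = rep(seq_len(nt), nv),
        x = as.vector(tx), y = as.vector(ty))
    }
    bleach <- exp(-params$bleach_rate_per_frame * (seq_len(nt) - 1))
    h <- ceiling(4 * sigma)
    for (t in seq_len(nt)) {
      fr <- matrix(params$background_level, shape[1], shape[2])
      if (nv > 0) {
        for (i in seq_len(nv)) {
          cy <- ty[t, i]; cx <- tx[t, i]
          y0 <- max(1, floor(cy) + 1 - h); y1 <- min(shape[1],
                                                     floor(cy) + 1 + h)
          x0 <- max(1, floor(cx) + 1 - h); x1 <- min(shape[2],
                                                     floor(cx) + 1 + h)
          yy <- (y0:y1) - 1; xx <- (x0:x1) - 1
          spot <- params$spot_peak *
            exp(-(outer((yy - cy)^2, (xx - cx)^2, `+`)) / (2 * sigma^2))
          fr[y0:y1, x0:x1] <- fr[y0:y1, x0:x1] + spot
        }
      }
      fr <- fr * bleach[t]
      arr[t, 1L, , ] <- apply_noise(fr, list(
        noise_model = params$noise_model,
        gaussian_sigma = params$gaussian_sigma))
    }
  })

  stack <- image_stack(arr, pixel_size_um = params$pixel_size_um,
                       frame_interval_s = params$frame_interval_s,
                       channel_names = "vesicles")
  truth <- structure(list(
    tracks_true = tracks,
    speed_true = if (nv > 0) params$speed_px_per_frame else numeric(0),
    bleach_rate_true = params$bleach_rate_per_frame,
    motion = params$motion, seed = params$seed
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}
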