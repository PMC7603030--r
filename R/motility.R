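#' Detect vesicle candidates in one frame
#'
#' Otsu-thresholds the (background-subtracted, bleach-corrected) frame
#' within the ROI, labels connected components and keeps those whose pixel
#' area lies within `[min_area_px, max_area_px]` — by default the 5-30 px
#' window used to define possible vesicles. Centroids are
#' intensity-weighted sub-pixel positions.
#'
#' @param frame_image numeric matrix `[y, x]`.
#' @param roi optional [cell_roi()]; default is the whole frame.
#' @param min_area_px,max_area_px inclusive component-area bounds.
#' @return Data frame with columns `x`, `y` (0-based pixel coordinates),
#'   `area_px`, `intensity` (summed over the component). A frame whose
#'   histogram is degenerate (e.g. blank after subtraction) propagates a
#'   degenerate-histogram error; pipeline callers convert that to zero
#'   detections.
#' @export
detect_vesicles <- function(frame_image, roi = NULL, min_area_px = 5L,
                            max_area_px = 30L) {
  check_matrix_image(frame_image, "frame_image")
  if (min_area_px >= max_area_px)
    stop_param("min_area_px must be < max_area_px")
  rmask <- if (is.null(roi)) matrix(TRUE, nrow(frame_image),
                                    ncol(frame_image)) else roi$mask
  vals <- frame_image[rmask]
  if (length(unique(vals)) < 2L)
    stop_degenerate("frame constant within ROI: Otsu undefined")
  thr <- otsu_threshold(matrix(vals, ncol = 1))$threshold
  mask <- (frame_image > thr) & rmask
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      area_px = integer(0), intensity = numeric(0)))
  idx <- which(lab > 0)
  labs <- lab[idx]
  w <- frame_image[idx]
  yy <- (idx - 1) %% nrow(frame_image)        # 0-based row
  xx <- (idx - 1) %/% nrow(frame_image)       # 0-based col
  area <- tabulate(labs, nbins = nlab)
  wsum <- vapply(split(w, labs), sum, 0)
  cx <- vapply(split(w * xx, labs), sum, 0) / wsum
  cy <- vapply(split(w * yy, labs), sum, 0) / wsum
  keep <- area >= min_area_px & area <= max_area_px
  data.frame(x = unname(cx[keep]), y = unname(cy[keep]),
             area_px = area[keep], intensity = unname(wsum[keep]))
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame assignment by greedy global-minimum (mutual-nearest)
#' matching: among all candidate pairs of open tracks and current
#' detections, the closest pair is linked first, then the next closest
#' among the remainder, and so on; links longer than `max_link_px` are
#' forbidden. A track left unmatched stays open for up to `max_gap_frames`
#' missed frames (gap closing); unlinked detections start new tracks.
#'
#' @param detections data frame with columns `frame`, `x`, `y` (any other
#'   columns are carried along).
#' @param max_link_px maximum link distance, pixels.
#' @param max_gap_frames frames a track may skip and still be continued.
#' @return Object of class `vesicle_tracks`: a data frame with columns
#'   `track_id`, `frame`, `x`, `y`, ordered by track then frame. Empty
#'   input gives an empty track table.
#' @export
link_tracks <- function(detections, max_link_px = 5, max_gap_frames = 1L) {
  cols <- c("frame", "x", "y")
  if (is.null(detections) || nrow(detections) == 0) {
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0))
    class(out) <- c("vesicle_tracks", "data.frame")
    return(out)
  }
  if (!all(cols %in% names(detections)))
    stop_input("detections need columns frame, x, y")
  det <- detections[order(detections$frame), cols]
  frames <- sort(unique(det$frame))
  # open tracks: id, last x/y, last frame
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0)
  tr_last <- integer(0)
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    d <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(d)
    open <- which(tr_last >= f - 1L - max_gap_frames & tr_last < f)
    assign_track <- integer(nd)
    if (length(open) > 0 && nd > 0) {
      dist <- outer(tr_x[open], d$x, `-`)^2 + outer(tr_y[open], d$y, `-`)^2
      dist <- sqrt(dist)
      dist[dist > max_link_px] <- Inf
      repeat {
        m <- which.min(dist)
        if (length(m) == 0 || !is.finite(dist[m])) break
        i <- (m - 1) %% length(open) + 1     # open-track row
        j <- (m - 1) %/% length(open) + 1    # detection col
        assign_track[j] <- open[i]
        dist[i, ] <- Inf
        dist[, j] <- Inf
      }
    }
    for (j in seq_len(nd)) {
      k <- assign_track[j]
      if (k == 0L) {
        k <- next_id
        next_id <- next_id + 1L
        tr_id[k] <- k; tr_x[k] <- NA_real_; tr_y[k] <- NA_real_
        tr_last[k] <- 0L
      }
      tr_x[k] <- d$x[j]; tr_y[k] <- d$y[j]; tr_last[k] <- f
      rows[[fi]] <- rbind(rows[[fi]],
                          data.frame(track_id = k, frame = f,
                                     x = d$x[j], y = d$y[j]))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0))
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("vesicle_tracks", "data.frame")
  out
}

#' Per-track motility statistics
#'
#' Mean speed is the total path length divided by the total elapsed frames
#' (robust to gap closing); displacement is the straight-line distance
#' between a track's first and last positions. Displacement never exceeds
#' path length.
#'
#' @param tracks a `vesicle_tracks` data frame.
#' @return Data frame with `track_id`, `n_points`, `first_frame`,
#'   `last_frame`, `path_length`, `mean_speed` (px/frame),
#'   `displacement` (px). Single-point tracks get speed 0, displacement 0.
#' @export
track_stats <- function(tracks) {
  if (nrow(tracks) == 0)
    return(data.frame(track_id = integer(0), n_points = integer(0),
                      first_frame = integer(0), last_frame = integer(0),
                      path_length = numeric(0), mean_speed = numeric(0),
                      displacement = numeric(0)))
  sp <- split(tracks, tracks$track_id)
  do.call(rbind, lapply(sp, function(tk) {
    tk <- tk[order(tk$frame), ]
    n <- nrow(tk)
    path <- if (n > 1) sum(sqrt(diff(tk$x)^2 + diff(tk$y)^2)) else 0
    elapsed <- tk$frame[n] - tk$frame[1]
    data.frame(track_id = tk$track_id[1], n_points = n,
               first_frame = tk$frame[1], last_frame = tk$frame[n],
               path_length = path,
               mean_speed = if (elapsed > 0) path / elapsed else 0,
               displacement = sqrt((tk$x[n] - tk$x[1])^2 +
                                     (tk$y[n] - tk$y[1])^2))
  }))
}

#' ROI-level MeanSpeed and MeanDisplacement
#'
#' MeanSpeed is the arithmetic mean, over all tracked vesicles in the ROI,
#' of each track's mean speed; MeanDisplacement is the arithmetic mean of
#' the tracks' first-to-last straight-line distances — a readout for
#' directed, long-distance transport. Tracks shorter than `min_track_len`
#' points are excluded. With calibration present the summaries are
#' reported in um/s and um; otherwise in px/frame and px.
#'
#' @param tracks a `vesicle_tracks` data frame.
#' @param roi_label integer label echoed into the summary.
#' @param pixel_size_um,frame_interval_s calibration (both needed for
#'   physical units).
#' @param min_track_len minimum points per eligible track (>= 2).
#' @return Object of class `motility_summary`: list with `roi_label`,
#'   `n_tracks`, `mean_speed`, `mean_displacement`, `units`, and the
#'   per-track table `per_track`. With no eligible tracks the summaries
#'   are `NA` (missing, not zero) and `n_tracks` is 0.
#' @export
summarize_motility <- function(tracks, roi_label = 1L,
                               pixel_size_um = NA_real_,
                               frame_interval_s = NA_real_,
                               min_track_len = 5L) {
  if (min_track_len < 2L) stop_param("min_track_len must be >= 2")
  st <- track_stats(tracks)
  st <- st[st$n_points >= min_track_len, , drop = FALSE]
  calibrated <- !is.na(pixel_size_um) && !is.na(frame_interval_s)
  units <- if (calibrated) "um_per_s" else "px_per_frame"
  if (nrow(st) == 0) {
    res <- list(roi_label = as.integer(roi_label), n_tracks = 0L,
                mean_speed = NA_real_, mean_displacement = NA_real_,
                units = units, per_track = st)
  } else {
    speed <- st$mean_speed
    disp <- st$displacement
    if (calibrated) {
      speed <- speed * pixel_size_um / frame_interval_s
      disp <- disp * pixel_size_um
    }
    res <- list(roi_label = as.integer(roi_label), n_tracks = nrow(st),
                mean_speed = mean(speed), mean_displacement = mean(disp),
                units = units, per_track = st)
  }
  class(res) <- "motility_summary"
  res
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("<motility_summary> ROI %d: %d track(s)\n", x$roi_label,
              x$n_tracks))
  cat(sprintf("  MeanSpeed: %s   MeanDisplacement: %s   [%s]\n",
              format(x$mean_speed, digits = 4),
              format(x$mean_displacement, digits = 4), x$units))
  invisible(x)
}

#' Full vesicle-motility pipeline for one movie
#'
#' Runs the fixed stage order: rolling-ball background subtraction,
#' exponential bleach correction, per-frame Otsu detection with the
#' 5-30 px size filter, nearest-neighbour linking, and the ROI-level
#' summary. Frames that come out blank (degenerate histogram) contribute
#' zero detections.
#'
#' @param stack single-channel [image_stack()] movie.
#' @param roi optional [cell_roi()].
#' @param rolling_ball_radius background radius, px.
#' @param bleach_correction logical; skip to study its effect.
#' @param min_area_px,max_area_px detection size filter.
#' @param max_link_px,max_gap_frames linking parameters.
#' @param min_track_len minimum track length for the summary.
#' @return List with `summary` ([summarize_motility()] result), `tracks`,
#'   `detections` (with `frame` column), and `bleach_fit` (or `NULL`).
#' @export
analyze_vesicle_movie <- function(stack, roi = NULL,
                                  rolling_ball_radius = 20,
                                  bleach_correction = TRUE,
                                  min_area_px = 5L, max_area_px = 30L,
                                  max_link_px = 5, max_gap_frames = 1L,
                                  min_track_len = 5L) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  work <- stack
  for (t in seq_len(nt))
    work$data[t, 1L, , ] <-
      rolling_ball_background_subtract(get_frame(stack, t),
                                       rolling_ball_radius)
  fit <- NULL
  if (bleach_correction) {
    bc <- bleach_correct(work)
    work <- bc$corrected
    fit <- bc$fit
  }
  dets <- vector("list", nt)
  for (t in seq_len(nt)) {
    d <- tryCatch(detect_vesicles(get_frame(work, t), roi,
                                  min_area_px, max_area_px),
                  secrflux_degenerate_error = function(e)
                    data.frame(x = numeric(0), y = numeric(0),
                               area_px = integer(0),
                               intensity = numeric(0)))
    if (nrow(d) > 0) d$frame <- t
    dets[[t]] <- d
  }
  dets <- do.call(rbind, dets[vapply(dets, nrow, 0L) > 0])
  tracks <- link_tracks(dets, max_link_px, max_gap_frames)
  summary <- summarize_motility(tracks,
                                roi_label = if (is.null(roi)) 1L
                                            else roi$label,
                                pixel_size_um = stack$pixel_size_um,
                                frame_interval_s = stack$frame_interval_s,
                                min_track_len = min_track_len)
  list(summary = summary, tracks = tracks, detections = dets,
       bleach_fit = fit)
}
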