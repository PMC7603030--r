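#' Multi-frame, multi-channel image stack with physical calibration
#'
#' Container for time-lapse fluorescence data. Pixel data are stored as a
#' 4-D numeric array indexed `[t, channel, y, x]` with non-negative, finite
#' intensities (interpreted as camera counts). Calibration metadata travel
#' with the pixels: pixel size in micrometres, frame interval in seconds,
#' and (for snapshot series) acquisition timepoints in minutes.
#'
#' @param data 4-D numeric array `[t, channel, y, x]`, or a matrix `[y, x]`
#'   (promoted to a single-frame, single-channel stack), or a 3-D array
#'   `[t, y, x]` (single channel).
#' @param pixel_size_um pixel size, micrometres per pixel (`NA` if unknown;
#'   downstream results are then reported in pixel/frame units).
#' @param frame_interval_s frame interval in seconds (`NA` if unknown).
#' @param timepoints_min optional numeric vector of acquisition times in
#'   minutes, one per frame, strictly increasing.
#' @param channel_names optional character vector of channel labels.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(runif(2 * 1 * 8 * 8), c(2, 1, 8, 8)),
#'                  frame_interval_s = 0.2)
#' s
#' @export
image_stack <- function(data, pixel_size_um = NA_real_,
                        frame_interval_s = NA_real_,
                        timepoints_min = NULL, channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, c(1L, 1L, nrow(data), ncol(data)))
  } else if (is.array(data) && length(dim(data)) == 3L) {
    data <- array(data, c(dim(data)[1L], 1L, dim(data)[2L], dim(data)[3L]))
  }
  if (!is.array(data) || length(dim(data)) != 4L || !is.numeric(data))
    stop_input("data must be a numeric array [t, channel, y, x]")
  if (any(!is.finite(data)))
    stop_input("image intensities must be finite")
  if (any(data < 0))
    stop_input("image intensities must be non-negative")
  if (!is.null(timepoints_min)) {
    if (length(timepoints_min) != dim(data)[1L])
      stop_input("timepoints_min must have one entry per frame")
    if (any(diff(timepoints_min) <= 0))
      stop_input("timepoints_min must be strictly increasing")
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  if (length(channel_names) != dim(data)[2L])
    stop_input("channel_names must have one entry per channel")
  structure(list(
    data = data,
    pixel_size_um = as.numeric(pixel_size_um),
    frame_interval_s = as.numeric(frame_interval_s),
    timepoints_min = timepoints_min,
    channel_names = as.character(channel_names)
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frame(s) x %d channel(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.na(x$pixel_size_um))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size_um))
  if (!is.na(x$frame_interval_s))
    cat(sprintf("  frame interval: %g s\n", x$frame_interval_s))
  if (!is.null(x$timepoints_min))
    cat("  timepoints (min):", paste(x$timepoints_min, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame of one channel as a plain matrix
#'
#' @param stack an [image_stack()].
#' @param frame 1-based frame index.
#' @param channel 1-based channel index or channel name.
#' @return Numeric matrix `[y, x]`.
#' @export
get_frame <- function(stack, frame = 1L, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop_input("unknown channel name")
  }
  d <- dim(stack$data)
  if (frame < 1L || frame > d[1L]) stop_input("frame index out of range")
  if (channel < 1L || channel > d[2L]) stop_input("channel index out of range")
  matrix(stack$data[frame, channel, , ], d[3L], d[4L])
}

n_frames <- function(stack) dim(stack$data)[1L]
n_channels <- function(stack) dim(stack$data)[2L]
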