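#' Rolling-ball style background subtraction
#'
#' Estimates the smooth, large-scale background of a fluorescence image by
#' grayscale morphological opening with a flat disc structuring element of
#' the given radius, and subtracts it. Structures narrower than the disc
#' (cells' puncta, vesicles, Golgi blobs on a flat field) survive; anything
#' the disc can "roll under" is treated as background. The estimated
#' background is bounded above by the image, so the result is non-negative
#' by construction; it is additionally clipped at zero to absorb floating
#' point round-off.
#'
#' @param image numeric matrix `[y, x]`.
#' @param radius_px structuring-element radius in pixels, >= 1. Must be
#'   smaller than the smaller image dimension. Default 50 px, a common
#'   cell-scale choice; expose it in provenance when it matters.
#' @return Numeric matrix, same shape, `image - background >= 0`.
#' @export
rolling_ball_background_subtract <- function(image, radius_px = 50) {
  check_matrix_image(image)
  if (!is.numeric(radius_px) || radius_px < 1)
    stop_param("radius_px must be >= 1")
  size <- 2L * as.integer(radius_px) + 1L
  if (size > min(dim(image)))
    stop_param("radius_px too large for the image (", radius_px, " px)")
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- grayscale_opening(image, brush)
  out <- image - bg
  out[out < 0] <- 0
  out
}
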