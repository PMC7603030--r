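#' Iterated binary erosion
#'
#' Erodes a binary mask `iterations` times with a 3x3 cross (4-connected)
#' structuring element, the classic macro default for peeling one boundary
#' pixel per pass. `iterations = 0` is the identity; output is always a
#' subset of the input.
#'
#' @param mask logical or 0/1 matrix.
#' @param iterations non-negative integer, number of erosion passes.
#' @param kernel `"cross"` (3x3, 4-connectivity, default) or `"box"`
#'   (3x3, 8-connectivity).
#' @return Logical matrix.
#' @export
erode_binary <- function(mask, iterations = 1L, kernel = c("cross", "box")) {
  mask <- check_binary_mask(mask)
  kernel <- match.arg(kernel)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop_param("iterations must be a non-negative integer")
  if (iterations == 0L || !any(mask)) return(mask)
  kern <- if (kernel == "cross") {
    matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  } else {
    matrix(1, 3, 3)
  }
  m <- mask * 1
  for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  m > 0.5
}

#' Binary opening (erosion then dilation)
#'
#' @param mask logical or 0/1 matrix.
#' @param brush_size odd integer size of the disc structuring element.
#' @return Logical matrix.
#' @export
open_binary <- function(mask, brush_size = 3L) {
  mask <- check_binary_mask(mask)
  if (!any(mask)) return(mask)
  kern <- EBImage::makeBrush(as.integer(brush_size), shape = "disc")
  EBImage::opening(mask * 1, kern) > 0.5
}
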