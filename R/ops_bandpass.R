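#' Spatial bandpass filter
#'
#' Suppresses image structure smaller than `small_px` and larger than
#' `large_px`. The default realization is a difference of Gaussians
#' (sigma = size / 2 for each cutoff), which removes the DC component and
#' large-scale shading while smoothing away sub-structure noise — the same
#' role the classic FFT bandpass plays in ImageJ-style filament masking. A
#' frequency-domain annulus (hard mask on spatial periods in
#' `[small_px, large_px]`) is available via `method = "fft"`.
#'
#' Both realizations are linear in the input.
#'
#' @param image numeric matrix `[y, x]`.
#' @param small_px suppress structures smaller than this size (pixels).
#' @param large_px suppress structures larger than this size (pixels);
#'   must exceed `small_px`.
#' @param method `"dog"` (difference of Gaussians, default) or `"fft"`.
#' @return Numeric matrix (zero-mean-ish; may contain negative values).
#' @export
bandpass_filter <- function(image, small_px = 3, large_px = 40,
                            method = c("dog", "fft")) {
  check_matrix_image(image)
  method <- match.arg(method)
  if (!(small_px > 0 && large_px > small_px))
    stop_param("need 0 < small_px < large_px")
  nr <- nrow(image); nc <- ncol(image)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f2 <- outer(fy^2, fx^2, `+`)
  if (method == "dog") {
    # exact Gaussian transfer functions applied in the frequency domain;
    # unlike a truncated spatial kernel this stays valid when the sigma is
    # comparable to the image size
    h <- function(sigma) exp(-2 * pi^2 * sigma^2 * f2)
    keep <- h(small_px / 2) - h(large_px / 2)
  } else {
    fr <- sqrt(f2)
    keep <- fr >= 1 / large_px & fr <= 1 / small_px
  }
  Re(stats::fft(stats::fft(image) * keep, inverse = TRUE)) / (nr * nc)
}
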