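#' Otsu threshold of a grayscale image
#'
#' Selects the intensity threshold that maximizes the between-class variance
#' of the image histogram (equivalently, minimizes the within-class
#' variance), the standard automatic bimodal threshold. Candidate thresholds
#' are the distinct gray levels present in the image; the returned mask is
#' `image > threshold`.
#'
#' @param image numeric matrix `[y, x]` with at least two distinct values.
#' @return A list with `threshold` (numeric scalar) and `mask`
#'   (logical matrix, `image > threshold`).
#' @details A constant image has a degenerate histogram: no threshold
#'   separates two classes, and an error of class
#'   `secrflux_degenerate_error` is raised so callers can decide their own
#'   fallback. Ties in the between-class variance are broken toward the
#'   lowest qualifying threshold.
#' @examples
#' img <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
#' otsu_threshold(img)$threshold
#' @export
otsu_threshold <- function(image) {
  check_matrix_image(image)
  v <- sort(unique(as.vector(image)))
  if (length(v) < 2L)
    stop_degenerate("constant image: Otsu threshold undefined")
  cnt <- tabulate(match(as.vector(image), v), nbins = length(v))
  n <- sum(cnt)
  p <- cnt / n
  omega <- cumsum(p)              # class-0 probability up to level k
  mu <- cumsum(p * v)             # first moment up to level k
  mu_t <- mu[length(mu)]
  # between-class variance for threshold at each level k (class 0: <= v[k])
  k <- seq_len(length(v) - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- (mu_t * omega[k] - mu[k])^2 / denom
  sigma_b[denom <= 0] <- -Inf
  thr <- v[which.max(sigma_b)]
  list(threshold = thr, mask = image > thr)
}

#' Local (sliding-window) Otsu threshold
#'
#' Computes, for every pixel, the Otsu threshold of the intensity histogram
#' in a centred square window (clamped at the image border) and marks the
#' pixel as foreground when its value exceeds its local threshold. This
#' adapts the threshold to local contrast, so dim structures in one part of
#' the image are not lost to bright structures elsewhere.
#'
#' @param image numeric matrix `[y, x]`.
#' @param window_px odd integer window side length, >= 3.
#' @param levels number of histogram bins used for the windowed histograms
#'   (intensities are binned linearly over the image range).
#' @return Logical matrix; pixels whose window is degenerate (a single
#'   occupied bin) are background.
#' @export
local_otsu_threshold <- function(image, window_px = 51L, levels = 256L) {
  check_matrix_image(image)
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop_param("window_px must be odd and >= 3")
  if (window_px > min(dim(image)))
    stop_param("window_px larger than the image")
  rng <- range(image)
  if (rng[1] == rng[2])
    return(matrix(FALSE, nrow(image), ncol(image)))
  out <- local_otsu_cpp(image, window_px, as.integer(levels))
  out > 0.5
}
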