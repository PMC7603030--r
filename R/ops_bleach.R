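#' Photobleaching correction by exponential fit
#'
#' Fluorophores bleach over a long acquisition, so later frames are dimmer
#' for reasons unrelated to biology; a per-frame intensity-adaptive detector
#' (e.g. an Otsu threshold on quantized camera counts) then behaves
#' differently across the movie. The correction fits a mono-exponential
#' with offset to the frame-mean intensities,
#' \deqn{m(t) \approx A e^{-k t} + c,}
#' (t in frames, 0-based) by variable projection — the rate is found by a
#' one-dimensional profile search, with the amplitude and offset solved
#' linearly — and rescales every frame by `m_hat(0) / m_hat(t)` so the
#' fitted mean trajectory is flat.
#'
#' @param stack an [image_stack()] with at least 3 frames (all channels are
#'   corrected with the fit from channel 1).
#' @return A list with `corrected` (an [image_stack()]) and `fit`
#'   (a `bleach_fit` object with `amplitude`, `rate_per_frame`, `offset`,
#'   `residual_rms`, `frame_means`, `fitted_means`).
#' @details A near-constant stack (relative spread of frame means below
#'   1e-6) is returned unchanged with `rate_per_frame = 0`. When the
#'   exponential does not beat a constant fit at the 1% level (F test) —
#'   typically a non-bleaching movie whose frame means fluctuate only with
#'   noise — the fit falls back to the constant model (`rate_per_frame =
#'   0`, no correction, `model = "constant"`). The fitted rate is
#'   constrained to be non-negative.
#' @examples
#' fr <- sapply(0:19, function(t) exp(-0.01 * t) * 100, simplify = FALSE)
#' arr <- aperm(array(unlist(lapply(fr, function(v) matrix(v, 8, 8))),
#'                    c(8, 8, 20)), c(3, 1, 2))
#' res <- bleach_correct(image_stack(arr))
#' res$fit$rate_per_frame
#' @export
bleach_correct <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  if (nt < 3L)
    stop_input("bleach correction needs at least 3 frames, got ", nt)
  m <- vapply(seq_len(nt), function(t) mean(stack$data[t, 1L, , ]), 0)
  tt <- seq_len(nt) - 1
  rel_spread <- (max(m) - min(m)) / max(mean(m), .Machine$double.eps)
  if (rel_spread < 1e-6) {
    fit <- new_bleach_fit(0, 0, mean(m), 0, m, rep(mean(m), nt))
    return(list(corrected = stack, fit = fit))
  }
  # Variable projection: for a fixed rate k the model is linear in (A, c),
  # so profile the residual sum of squares over k alone. A joint
  # 3-parameter nonlinear fit is numerically rank-deficient for slow
  # decays — exp(-kt) ~ 1 - kt makes d/dA a linear combination of the
  # offset and rate gradients — and fails on even noise-free data.
  rss_k <- function(k) {
    sum(stats::lm.fit(cbind(exp(-k * tt), 1), m)$residuals^2)
  }
  opt <- stats::optimize(rss_k, c(1e-8, 2), tol = 1e-10)
  k_hat <- opt$minimum
  cf <- stats::lm.fit(cbind(exp(-k_hat * tt), 1), m)$coefficients
  rss1 <- opt$objective
  rss0 <- sum((m - mean(m))^2)
  # accept the exponential only when it beats the constant model at the
  # 1% level (F test, 2 extra parameters); otherwise a noisy but
  # non-bleaching movie would receive a spurious correction
  f_stat <- ((rss0 - rss1) / 2) / (rss1 / max(nt - 3, 1))
  p_f <- stats::pf(f_stat, 2, max(nt - 3, 1), lower.tail = FALSE)
  if (!is.finite(cf[[1]]) || cf[[1]] <= 0 || isTRUE(p_f > 0.01)) {
    fit <- new_bleach_fit(0, 0, mean(m), sqrt(rss0 / nt), m,
                          rep(mean(m), nt), model = "constant")
    return(list(corrected = stack, fit = fit))
  }
  fitted_m <- cf[[1]] * exp(-k_hat * tt) + cf[[2]]
  if (any(!is.finite(fitted_m)) || any(fitted_m <= 0))
    stop_input("bleach fit produced non-positive fitted means")
  rms <- sqrt(rss1 / nt)
  fit <- new_bleach_fit(cf[[1]], k_hat, cf[[2]], rms, m, fitted_m)
  corr <- stack
  scale <- fitted_m[1] / fitted_m
  for (t in seq_len(nt)) corr$data[t, , , ] <- stack$data[t, , , ] * scale[t]
  list(corrected = corr, fit = fit)
}

new_bleach_fit <- function(A, k, c, rms, m, fitted_m,
                           model = "exponential") {
  structure(list(amplitude = as.numeric(A), rate_per_frame = as.numeric(k),
                 offset = as.numeric(c), residual_rms = as.numeric(rms),
                 frame_means = m, fitted_means = fitted_m, model = model),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf(
    "<bleach_fit> m(t) = %.4g * exp(-%.4g t) + %.4g  (residual RMS %.4g)\n",
    x$amplitude, x$rate_per_frame, x$offset, x$residual_rms))
  invisible(x)
}

#' @export
plot.bleach_fit <- function(x, ...) {
  tt <- seq_along(x$frame_means) - 1
  plot(tt, x$frame_means, xlab = "frame", ylab = "frame mean intensity",
       pch = 20, cex = 0.5, ...)
  lines(tt, x$fitted_means, col = "red", lwd = 2)
  invisible(x)
}
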