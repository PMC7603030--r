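# Independent oracles and small constructors shared across tests.

# Exhaustive Otsu: try every observed gray level as the threshold and keep
# the one maximizing between-class variance (ties -> lowest level).
brute_force_otsu <- function(img) {
  v <- sort(unique(as.vector(img)))
  n <- length(img)
  best <- -Inf
  thr <- v[1]
  for (k in v[-length(v)]) {
    lo <- img[img <= k]
    hi <- img[img > k]
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {
      best <- sb
      thr <- k
    }
  }
  thr
}

# Rasterized disc mask of radius r (pixel centers within r of the center).
disc_mask <- function(r, pad = 5L) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- r + pad + 1L
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix((g$y - c0)^2 + (g$x - c0)^2 <= r^2, n, n)
}

# Single-channel image_stack from a list of frame matrices.
stack_from_frames <- function(frames, ...) {
  d <- dim(frames[[1]])
  arr <- array(0, c(length(frames), 1L, d[1], d[2]))
  for (t in seq_along(frames)) arr[t, 1L, , ] <- frames[[t]]
  image_stack(arr, ...)
}

# Planted mean speed (px/frame) from a summarize_motility result computed
# on a calibrated stack.
speed_in_px_per_frame <- function(summary, pixel_size_um,
                                  frame_interval_s) {
  if (identical(summary$units, "um_per_s"))
    summary$mean_speed * frame_interval_s / pixel_size_um
  else summary$mean_speed
}

displacement_in_px <- function(summary, pixel_size_um) {
  if (identical(summary$units, "um_per_s"))
    summary$mean_displacement / pixel_size_um
  else summary$mean_displacement
}
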