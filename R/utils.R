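# internal helpers shared across modules

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) {
  stop(structure(class = c("secrflux_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("secrflux_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("secrflux_degenerate_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_matrix_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_input(arg, " must be a numeric matrix (y, x)")
  if (any(!is.finite(image)))
    stop_input(arg, " contains non-finite values")
  invisible(image)
}

check_binary_mask <- function(mask, arg = "mask") {
  if (is.logical(mask)) return(matrix(mask, nrow(mask), ncol(mask)))
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop_input(arg, " must be a logical or 0/1 matrix")
  mask > 0
}

# EBImage stores images as (x, y); package convention is matrix [y, x].
# Symmetric kernels make the transpose a no-op for the operators used here,
# so matrices are passed straight through.

# grayscale morphology wrapper: EBImage::erode clamps grayscale input to
# [0, 1] (dilate does not), so normalize, operate, rescale
grayscale_opening <- function(image, brush) {
  mx <- max(image)
  if (mx <= 0) return(image * 0)
  x <- image / mx
  EBImage::dilate(EBImage::erode(x, brush), brush) * mx
}
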