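#' Ratiometric biosensor trace
#'
#' A time series of dimensionless ratio values (FRET acceptor/donor, or
#' Fura-2 340/385 excitation ratio) with a designated basal window — the
#' stable baseline recorded before any stimulus.
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param ratio positive, finite ratio values, one per sample.
#' @param basal_window_s `c(start, end)` of the basal window, seconds;
#'   must lie within the trace's time span.
#' @return An object of class `ratio_trace`.
#' @export
ratio_trace <- function(time_s, ratio, basal_window_s = c(0, 300)) {
  if (length(time_s) != length(ratio))
    stop_input("time_s and ratio differ in length")
  if (any(diff(time_s) <= 0))
    stop_input("time_s must be strictly increasing")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop_input("ratio values must be finite and > 0")
  if (basal_window_s[1] > basal_window_s[2] ||
      basal_window_s[1] < time_s[1] - 1e-9 ||
      basal_window_s[2] > time_s[length(time_s)] + 1e-9)
    stop_input("basal window must lie within the trace's time span")
  structure(list(time_s = as.numeric(time_s), ratio = as.numeric(ratio),
                 basal_window_s = as.numeric(basal_window_s)),
            class = "ratio_trace")
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf(
    "<ratio_trace> %d samples over %g s (basal window %g-%g s)\n",
    length(x$time_s), diff(range(x$time_s)), x$basal_window_s[1],
    x$basal_window_s[2]))
  invisible(x)
}

#' @export
plot.ratio_trace <- function(x, ...) {
  plot(x$time_s, x$ratio, type = "l", xlab = "time (s)", ylab = "ratio",
       ...)
  abline(v = x$basal_window_s, lty = 3, col = "grey40")
  invisible(x)
}

#' Pointwise ratio of two time-aligned channel traces
#'
#' @param time_s shared sample times.
#' @param numerator,denominator channel intensities; the denominator must
#'   be strictly positive everywhere (the error names the first offending
#'   sample).
#' @param basal_window_s passed to [ratio_trace()].
#' @return A [ratio_trace()].
#' @export
compute_ratio <- function(time_s, numerator, denominator,
                          basal_window_s = c(0, 300)) {
  if (length(time_s) != length(numerator) ||
      length(numerator) != length(denominator))
    stop_input("time and channel vectors are misaligned")
  bad <- which(!is.finite(denominator) | denominator <= 0)
  if (length(bad) > 0)
    stop_input("denominator is zero/negative at sample index ", bad[1])
  ratio_trace(time_s, numerator / denominator, basal_window_s)
}

#' Maximal ratio change between basal level and an endpoint
#'
#' Basal level is the arithmetic mean over the basal window; the endpoint
#' is the single sample nearest the requested time (the actual time used
#' is echoed back). The sign convention follows the usual reporting of
#' biosensor declines: positive change = decline from basal.
#'
#' @param trace a [ratio_trace()].
#' @param endpoint_s requested endpoint time, seconds; must not precede
#'   the end of the basal window and must lie within the trace.
#' @return List with `change` (`basal_mean - endpoint_value`),
#'   `basal_mean`, `endpoint_value`, `endpoint_time_s` (actual).
#' @export
max_ratio_change <- function(trace, endpoint_s) {
  stopifnot(inherits(trace, "ratio_trace"))
  if (endpoint_s < trace$basal_window_s[2])
    stop_input("endpoint precedes the end of the basal window")
  if (endpoint_s > trace$time_s[length(trace$time_s)] + 1e-9)
    stop_input("endpoint lies beyond the trace")
  in_basal <- trace$time_s >= trace$basal_window_s[1] &
    trace$time_s <= trace$basal_window_s[2]
  if (!any(in_basal)) stop_input("no samples in the basal window")
  basal <- mean(trace$ratio[in_basal])
  idx <- which.min(abs(trace$time_s - endpoint_s))
  list(change = basal - trace$ratio[idx], basal_mean = basal,
       endpoint_value = trace$ratio[idx],
       endpoint_time_s = trace$time_s[idx])
}

#' Per-epoch extrema and deltas of a stimulus protocol
#'
#' For each labelled, non-overlapping epoch (e.g. basal / agonist /
#' washout), reports the minimum and maximum ratio and the maximum
#' absolute deviation from the reference level — the last sample before
#' the epoch starts (capturing, e.g., ER Ca2+ depletion depth or the
#' height of a cytosolic transient). The first epoch, if nothing precedes
#' it, is referenced to the basal-window mean.
#'
#' @param trace a [ratio_trace()].
#' @param epochs data frame with columns `label`, `start_s`, `end_s`,
#'   in increasing, non-overlapping order, within the trace span.
#' @return Data frame with `label`, `start_s`, `end_s`, `n`, `min`,
#'   `max`, `reference`, `max_deviation`.
#' @export
stimulus_response <- function(trace, epochs) {
  stopifnot(inherits(trace, "ratio_trace"))
  need <- c("label", "start_s", "end_s")
  if (!is.data.frame(epochs) || !all(need %in% names(epochs)))
    stop_input("epochs need columns label, start_s, end_s")
  if (nrow(epochs) < 1L) stop_input("epochs is empty")
  if (any(epochs$end_s < epochs$start_s))
    stop_input("epoch ends precede starts")
  if (nrow(epochs) > 1) {
    if (any(diff(epochs$start_s) <= 0) ||
        any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)]))
      stop_input("epochs must be ordered and non-overlapping")
  }
  tmax <- trace$time_s[length(trace$time_s)]
  if (epochs$start_s[1] < trace$time_s[1] - 1e-9 ||
      epochs$end_s[nrow(epochs)] > tmax + 1e-9)
    stop_input("epochs must lie within the trace")
  out <- lapply(seq_len(nrow(epochs)), function(i) {
    sel <- trace$time_s >= epochs$start_s[i] &
      trace$time_s <= epochs$end_s[i]
    if (!any(sel)) stop_input("epoch '", epochs$label[i], "' is empty")
    before <- which(trace$time_s < epochs$start_s[i])
    ref <- if (length(before) > 0) trace$ratio[max(before)] else {
      in_basal <- trace$time_s >= trace$basal_window_s[1] &
        trace$time_s <= trace$basal_window_s[2]
      mean(trace$ratio[in_basal])
    }
    v <- trace$ratio[sel]
    data.frame(label = epochs$label[i], start_s = epochs$start_s[i],
               end_s = epochs$end_s[i], n = sum(sel), min = min(v),
               max = max(v), reference = ref,
               max_deviation = max(abs(v - ref)))
  })
  do.call(rbind, out)
}

#' Read a ratio trace from CSV
#'
#' Accepts either a precomputed `ratio` column or two channel columns to
#' divide. Column `time_s` is required.
#'
#' @param path CSV file path.
#' @param numerator,denominator channel column names (used when `ratio`
#'   is absent).
#' @param basal_window_s passed to [ratio_trace()].
#' @return A [ratio_trace()].
#' @export
read_ratio_trace <- function(path, numerator = NULL, denominator = NULL,
                             basal_window_s = c(0, 300)) {
  df <- read.csv(path)
  if (!"time_s" %in% names(df)) stop_input("CSV lacks a time_s column")
  if ("ratio" %in% names(df))
    return(ratio_trace(df$time_s, df$ratio, basal_window_s))
  if (is.null(numerator) || is.null(denominator))
    stop_input("CSV lacks a ratio column; name numerator/denominator")
  compute_ratio(df$time_s, df[[numerator]], df[[denominator]],
                basal_window_s)
}

#' Write a ratio trace to CSV
#'
#' The written file round-trips: reading it back reproduces the trace
#' values exactly (full precision).
#'
#' @param trace a [ratio_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ratio_trace"))
  df <- data.frame(time_s = trace$time_s, ratio = trace$ratio)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
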