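#' Per-cell region of interest
#'
#' A cell footprint within which all per-cell statistics are computed. ROIs
#' are captured manually in practice and supplied as label masks; the
#' simulator's ground-truth cell masks substitute for manual drawing.
#'
#' @param label positive integer cell label.
#' @param mask logical or 0/1 matrix, non-empty.
#' @param source `"manual_file"` or `"ground_truth"`.
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(label, mask, source = c("manual_file",
                                             "ground_truth")) {
  source <- match.arg(source)
  mask <- check_binary_mask(mask)
  if (!any(mask)) stop_input("ROI mask is empty")
  if (!is.numeric(label) || label < 1)
    stop_input("ROI label must be a positive integer")
  structure(list(label = as.integer(label), mask = mask, source = source),
            class = "cell_roi")
}

#' Cell-free background region from a set of ROIs
#'
#' The complement of all cell footprints, optionally eroded to keep clear
#' of cell edges. Useful as the `background_mask` reference of
#' [compute_transport_index()].
#'
#' @param rois list of [cell_roi()] objects (or a single one).
#' @param margin_px erosion iterations applied to the complement (3x3
#'   cross), pushing the region away from cell boundaries.
#' @return Logical matrix.
#' @export
background_region <- function(rois, margin_px = 2L) {
  if (inherits(rois, "cell_roi")) rois <- list(rois)
  stopifnot(length(rois) > 0, all(vapply(rois, inherits, TRUE,
                                         "cell_roi")))
  any_cell <- Reduce(`|`, lapply(rois, `[[`, "mask"))
  bg <- !any_cell
  if (margin_px > 0) bg <- erode_binary(bg, margin_px, kernel = "cross")
  if (!any(bg)) stop_degenerate("no cell-free background region left")
  bg
}

#' Golgi mask from the marker channel
#'
#' Reproduces the masking recipe applied to the red Golgi-marker images:
#' rolling-ball background subtraction, Otsu threshold computed from the
#' pixels inside the cell ROI, then two binary erosions (3x3 cross). The
#' returned mask is a subset of the ROI; it is recomputed for every
#' timepoint's marker frame by [compute_transport_index()].
#'
#' @param golgi_marker_image numeric matrix, the marker frame.
#' @param roi a [cell_roi()].
#' @param rolling_ball_radius background-subtraction radius, px.
#' @param erode_iterations number of erosion passes (default 2).
#' @return Logical matrix.
#' @details A marker that is constant within the ROI raises a
#'   degenerate-histogram error; a mask that is empty after erosion raises
#'   a degenerate-mask error. Neither is silently recovered — callers
#'   decide the fallback.
#' @export
compute_golgi_mask <- function(golgi_marker_image, roi,
                               rolling_ball_radius = 50,
                               erode_iterations = 2L) {
  check_matrix_image(golgi_marker_image, "golgi_marker_image")
  stopifnot(inherits(roi, "cell_roi"))
  if (!all(dim(golgi_marker_image) == dim(roi$mask)))
    stop_input("marker image and ROI mask differ in shape")
  bg <- rolling_ball_background_subtract(golgi_marker_image,
                                         rolling_ball_radius)
  vals <- bg[roi$mask]
  if (length(unique(vals)) < 2L)
    stop_degenerate("marker constant within ROI: Otsu undefined")
  ot <- otsu_threshold(matrix(vals, ncol = 1))
  mask <- (bg > ot$threshold) & roi$mask
  mask <- erode_binary(mask, erode_iterations, kernel = "cross")
  if (!any(mask))
    stop_degenerate("Golgi mask empty after erosion")
  mask
}

#' Per-cell ER-to-Golgi transport index over time
#'
#' For each timepoint, a Golgi mask is derived from that timepoint's marker
#' frame ([compute_golgi_mask()]) and the cargo channel is split into Golgi
#' and non-Golgi regions within the cell ROI. The transport index is the
#' integrated-density ratio
#' \deqn{raw(t) = \frac{\sum_{Golgi} cargo_t}{\sum_{ROI
#'   \setminus Golgi} cargo_t}, \qquad TI(t) = raw(t) / raw(t_0),}
#' a variable starting at 1 and increasing as cargo redistributes from the
#' ER into the Golgi. The ratio is invariant to rescaling the cargo
#' channel.
#'
#' @param cargo_stack single-channel [image_stack()] of the cargo (GFP)
#'   channel, one frame per timepoint.
#' @param marker_stack single-channel [image_stack()] of the Golgi marker
#'   (RFP) channel, aligned with `cargo_stack`.
#' @param roi a [cell_roi()].
#' @param cargo_type `"soluble"` or `"transmembrane"` (decides the later
#'   classification time and thresholds).
#' @param cargo_background_radius rolling-ball radius for the cargo
#'   channel. It must exceed the cell footprint radius so that diffuse
#'   cell-wide ER signal is retained while the flat camera background is
#'   removed; default 90 px. `NA` skips cargo background subtraction.
#' @param marker_background_radius rolling-ball radius for the marker
#'   channel (passed to [compute_golgi_mask()]).
#' @param erode_iterations erosions applied to the Golgi mask.
#' @param background_mask optional logical matrix marking a cell-free
#'   region of the frame. Under shot noise the rolling-ball (morphological
#'   opening) background estimate is biased low — it tracks local minima —
#'   which leaves a positive per-pixel pedestal in the subtracted image.
#'   The pedestal inflates the small Golgi numerator at the first
#'   timepoint and so attenuates the whole normalized trajectory. When a
#'   cell-free reference region is supplied, its median residual is
#'   subtracted from every region sum (classic background-ROI
#'   referencing), removing the bias. With noise-free input the pedestal
#'   is zero and the correction is a no-op.
#' @return An object of class `ti_trajectory`: a data frame with columns
#'   `time_min`, `raw_ratio`, `ti`, plus attributes `cell_label`,
#'   `cargo_type` and `golgi_masks` (one logical mask per timepoint, for
#'   inspection and mask-quality checks).
#' @examples
#' sim <- generate_transport_series(scene_params(seed = 1),
#'                                  kinetics_preset("high", "soluble"))
#' roi <- cell_roi(1, sim$truth$cell_masks_true == 1, "ground_truth")
#' ch <- split_channels(sim$stack)
#' ti <- compute_transport_index(ch$cargo, ch$golgi_marker, roi, "soluble")
#' ti
#' @export
compute_transport_index <- function(cargo_stack, marker_stack, roi,
                                    cargo_type = c("soluble",
                                                   "transmembrane"),
                                    cargo_background_radius = 90,
                                    marker_background_radius = 50,
                                    erode_iterations = 2L,
                                    background_mask = NULL) {
  cargo_type <- match.arg(cargo_type)
  stopifnot(inherits(cargo_stack, "image_stack"),
            inherits(marker_stack, "image_stack"),
            inherits(roi, "cell_roi"))
  if (!is.null(background_mask)) {
    background_mask <- check_binary_mask(background_mask,
                                         "background_mask")
    if (!all(dim(background_mask) == dim(roi$mask)))
      stop_input("background_mask and ROI mask differ in shape")
    if (any(background_mask & roi$mask))
      stop_input("background_mask overlaps the cell ROI")
    if (!any(background_mask))
      stop_input("background_mask is empty")
  }
  nt <- n_frames(cargo_stack)
  if (nt != n_frames(marker_stack))
    stop_input("cargo and marker stacks differ in frame count")
  if (!identical(cargo_stack$timepoints_min, marker_stack$timepoints_min))
    stop_input("cargo and marker stacks have mismatched timepoints")
  tp <- cargo_stack$timepoints_min
  if (is.null(tp)) tp <- seq_len(nt) - 1

  raw <- numeric(nt)
  gmasks <- vector("list", nt)
  for (t in seq_len(nt)) {
    cargo <- get_frame(cargo_stack, t)
    marker <- get_frame(marker_stack, t)
    if (!is.na(cargo_background_radius))
      cargo <- rolling_ball_background_subtract(cargo,
                                                cargo_background_radius)
    gmask <- compute_golgi_mask(marker, roi,
                                rolling_ball_radius =
                                  marker_background_radius,
                                erode_iterations = erode_iterations)
    gmasks[[t]] <- gmask
    pedestal <- if (is.null(background_mask)) 0
                else median(cargo[background_mask])
    i_golgi <- sum(cargo[gmask]) - pedestal * sum(gmask)
    i_non <- sum(cargo[roi$mask & !gmask]) -
      pedestal * sum(roi$mask & !gmask)
    if (i_non <= 0)
      stop_input("zero non-Golgi integrated intensity at timepoint ", t)
    raw[t] <- i_golgi / i_non
  }
  out <- data.frame(time_min = tp, raw_ratio = raw, ti = raw / raw[1])
  structure(out, class = c("ti_trajectory", "data.frame"),
            cell_label = roi$label, cargo_type = cargo_type,
            golgi_masks = gmasks)
}

#' @export
print.ti_trajectory <- function(x, ...) {
  cat(sprintf("<ti_trajectory> cell %d (%s cargo)\n",
              attr(x, "cell_label"), attr(x, "cargo_type")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.ti_trajectory <- function(x, ...) {
  plot(x$time_min, x$ti, type = "b", xlab = "time after initiation (min)",
       ylab = "transport index", pch = 19, ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

# class thresholds: intervals are half-open [lower, upper), boundary values
# go to the higher class
.ti_classes <- list(
  soluble = list(decision_time_min = 30,
                 thresholds = c(very_high = 10, high = 5, moderate = 2)),
  transmembrane = list(decision_time_min = 15,
                       thresholds = c(very_high = 10, high = 7,
                                      moderate = 4)))

#' Classify transport efficiency from a TI trajectory
#'
#' Applies the four-class transport-efficiency scheme: for soluble cargo
#' the decision is made on the transport index at 30 min with class bounds
#' 10 / 5 / 2; for transmembrane cargo at 15 min with bounds 10 / 7 / 4.
#' Intervals are half-open, `[lower, upper)`, so a cell sitting exactly on
#' a bound is assigned to the higher class.
#'
#' @param traj a `ti_trajectory` from [compute_transport_index()], or a
#'   data frame with columns `time_min` and `ti` (then supply
#'   `cargo_type`).
#' @param cargo_type used when `traj` carries no cargo-type attribute.
#' @return An object of class `transport_class`: list with `label` (one of
#'   `"very_high"`, `"high"`, `"moderate"`, `"none"`), `cargo_type`,
#'   `decision_time_min`, `ti_at_decision`, `thresholds`.
#' @export
classify_transport <- function(traj, cargo_type = NULL) {
  if (is.null(cargo_type)) cargo_type <- attr(traj, "cargo_type")
  if (is.null(cargo_type))
    stop_input("cargo_type not given and not carried by the trajectory")
  cargo_type <- match.arg(cargo_type, c("soluble", "transmembrane"))
  spec <- .ti_classes[[cargo_type]]
  idx <- which(abs(traj$time_min - spec$decision_time_min) < 1e-9)
  if (length(idx) != 1L)
    stop_input("trajectory lacks the decision timepoint (",
               spec$decision_time_min, " min) for ", cargo_type, " cargo")
  ti <- traj$ti[idx]
  th <- spec$thresholds
  label <- if (ti >= th["very_high"]) "very_high"
  else if (ti >= th["high"]) "high"
  else if (ti >= th["moderate"]) "moderate"
  else "none"
  structure(list(label = label, cargo_type = cargo_type,
                 decision_time_min = spec$decision_time_min,
                 ti_at_decision = ti, thresholds = th),
            class = "transport_class")
}

#' @export
print.transport_class <- function(x, ...) {
  cat(sprintf("<transport_class> %s (%s cargo, TI = %.3g at %g min)\n",
              x$label, x$cargo_type, x$ti_at_decision,
              x$decision_time_min))
  invisible(x)
}

#' Population summary of TI trajectories
#'
#' Per-timepoint mean and SEM of the transport index across cells, plus a
#' class-frequency table (counts and percentages over the four
#' transport-efficiency classes).
#'
#' @param trajs list of `ti_trajectory` objects (same cargo type and
#'   timepoint schedule).
#' @param condition optional condition label echoed into the tables.
#' @return A list with `timecourse` (`time_min`, `mean_ti`, `sem_ti`, `n`;
#'   SEM is reported as 0 with `n = 1`) and `class_freq`
#'   (`class`, `count`, `pct`).
#' @export
summarize_population <- function(trajs, condition = NA_character_) {
  if (length(trajs) < 1L) stop_input("need at least one trajectory")
  types <- unique(vapply(trajs, function(x) attr(x, "cargo_type"), ""))
  if (length(types) != 1L)
    stop_input("trajectories mix cargo types; summarize separately")
  tp <- trajs[[1]]$time_min
  ok <- vapply(trajs, function(x) isTRUE(all.equal(x$time_min, tp)), TRUE)
  if (!all(ok)) stop_input("trajectories have mismatched timepoints")
  ti_mat <- vapply(trajs, function(x) x$ti, numeric(length(tp)))
  ti_mat <- matrix(ti_mat, nrow = length(tp))
  n <- ncol(ti_mat)
  mean_ti <- rowMeans(ti_mat)
  sem_ti <- if (n > 1) apply(ti_mat, 1, sd) / sqrt(n) else rep(0, length(tp))
  timecourse <- data.frame(condition = condition, time_min = tp,
                           mean_ti = mean_ti, sem_ti = sem_ti, n = n)
  labels <- vapply(trajs, function(x) classify_transport(x)$label, "")
  lv <- c("very_high", "high", "moderate", "none")
  cnt <- table(factor(labels, levels = lv))
  class_freq <- data.frame(condition = condition, class = lv,
                           count = as.integer(cnt),
                           pct = 100 * as.integer(cnt) / n)
  list(timecourse = timecourse, class_freq = class_freq,
       cargo_type = types)
}

#' Chi-square comparison of class frequencies between two conditions
#'
#' Delegates to [stats::chisq.test()] on the 2 x 4 contingency table of
#' transport-class counts (classes with zero counts in both conditions are
#' dropped).
#'
#' @param summary_a,summary_b results of [summarize_population()].
#' @return The `htest` object from [stats::chisq.test()].
#' @export
compare_class_frequencies <- function(summary_a, summary_b) {
  tab <- rbind(summary_a$class_freq$count, summary_b$class_freq$count)
  colnames(tab) <- summary_a$class_freq$class
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  stats::chisq.test(tab)
}

#' Split a multi-channel stack into single-channel stacks
#'
#' @param stack an [image_stack()].
#' @return Named list of single-channel `image_stack` objects.
#' @export
split_channels <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  out <- lapply(seq_len(d[2]), function(ch) {
    image_stack(array(stack$data[, ch, , , drop = FALSE],
                      c(d[1], 1L, d[3], d[4])),
                pixel_size_um = stack$pixel_size_um,
                frame_interval_s = stack$frame_interval_s,
                timepoints_min = stack$timepoints_min,
                channel_names = stack$channel_names[ch])
  })
  names(out) <- stack$channel_names
  out
}
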