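#' Read a TIFF file (or one file per channel) into an image stack
#'
#' Pages of a multi-page TIFF become frames; several paths become
#' channels (one file per channel), or a single file can hold interleaved
#' channels (`n_channels > 1`: pages cycle channel-fastest). Pixel values
#' are read as stored integer counts (`as.is = TRUE`). Calibration comes
#' from a JSON sidecar (`<path>.json`, written by [write_stack()]) when
#' present; explicit arguments override the sidecar (with a warning) and
#' missing calibration is flagged as `NA`, leaving downstream results in
#' pixel/frame units.
#'
#' @param paths one TIFF path, or one per channel.
#' @param n_channels interleaved channel count within a single file.
#' @param pixel_size_um,frame_interval_s,timepoints_min calibration
#'   overrides.
#' @param channel_names optional channel labels.
#' @return An [image_stack()].
#' @export
read_stack <- function(paths, n_channels = 1L, pixel_size_um = NA_real_,
                       frame_interval_s = NA_real_, timepoints_min = NULL,
                       channel_names = NULL) {
  for (p in paths) if (!file.exists(p)) stop_input("no such file: ", p)
  pages <- lapply(paths, function(p) {
    pg <- tryCatch(tiff::readTIFF(p, all = TRUE, as.is = TRUE),
                   error = function(e)
                     stop_input("unreadable TIFF '", p, "': ",
                                conditionMessage(e)))
    if (!is.list(pg)) pg <- list(pg)
    pg
  })
  meta <- read_sidecar(paths[1])
  ovr <- list(pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              timepoints_min = timepoints_min)
  for (f in names(ovr)) {
    given <- !is.null(ovr[[f]]) && !all(is.na(ovr[[f]]))
    if (!given) next
    if (!is.null(meta[[f]]) && !all(is.na(meta[[f]])) &&
        !isTRUE(all.equal(as.numeric(meta[[f]]), as.numeric(ovr[[f]]))))
      warning("calibration override for ", f,
              " conflicts with file metadata; override wins")
    meta[[f]] <- ovr[[f]]
  }
  if (length(paths) > 1L) {
    nt <- length(pages[[1]])
    if (any(vapply(pages, length, 0L) != nt))
      stop_input("channel files differ in page count")
    arr <- array(0, c(nt, length(paths), nrow(pages[[1]][[1]]),
                      ncol(pages[[1]][[1]])))
    for (ch in seq_along(pages))
      for (t in seq_len(nt)) arr[t, ch, , ] <- pages[[ch]][[t]]
  } else {
    pg <- pages[[1]]
    if (n_channels == 1L && !is.null(meta$n_channels))
      n_channels <- meta$n_channels
    n_channels <- as.integer(n_channels)
    if (length(pg) %% n_channels != 0L)
      stop_input("page count not divisible by n_channels")
    nt <- length(pg) %/% n_channels
    arr <- array(0, c(nt, n_channels, nrow(pg[[1]]), ncol(pg[[1]])))
    k <- 1L
    for (t in seq_len(nt)) for (ch in seq_len(n_channels)) {
      arr[t, ch, , ] <- pg[[k]]; k <- k + 1L
    }
  }
  if (is.null(channel_names)) channel_names <- meta$channel_names
  image_stack(arr,
              pixel_size_um = if (is.null(meta$pixel_size_um)) NA_real_
                              else meta$pixel_size_um,
              frame_interval_s = if (is.null(meta$frame_interval_s))
                NA_real_ else meta$frame_interval_s,
              timepoints_min = meta$timepoints_min,
              channel_names = channel_names)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write an image stack as 16-bit multi-page TIFF
#'
#' Intensities are rounded to integer counts (they must fit in 0..65535)
#' so that write/read round-trips are bit-exact. Channels go either to
#' separate files (suffix `_<channel>` before the extension) or
#' interleaved into one file, channel-fastest. Calibration is written to a
#' JSON sidecar next to the (first) TIFF.
#'
#' @param stack an [image_stack()].
#' @param path output path (`.tif`).
#' @param interleave write channels interleaved into a single file
#'   (default) instead of one file per channel.
#' @return Character vector of the files written, invisibly.
#' @export
write_stack <- function(stack, path, interleave = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$data) > 65535)
    stop_input("intensities exceed the 16-bit range")
  d <- dim(stack$data)
  to_page <- function(t, ch)
    round(matrix(stack$data[t, ch, , ], d[3], d[4])) / 65535
  files <- character(0)
  if (interleave || d[2] == 1L) {
    pages <- list()
    for (t in seq_len(d[1])) for (ch in seq_len(d[2]))
      pages[[length(pages) + 1L]] <- to_page(t, ch)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    files <- path
  } else {
    for (ch in seq_len(d[2])) {
      p <- sub("(\\.[^.]+)$", paste0("_", stack$channel_names[ch], "\\1"),
               path)
      pages <- lapply(seq_len(d[1]), to_page, ch = ch)
      tiff::writeTIFF(pages, p, bits.per.sample = 16L)
      files <- c(files, p)
    }
  }
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               timepoints_min = stack$timepoints_min,
               channel_names = stack$channel_names,
               n_channels = if (interleave) d[2] else 1L)
  meta <- Filter(function(v) !is.null(v) && !all(is.na(v)), meta)
  jsonlite::write_json(meta, paste0(files[1], ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(files)
}

#' Read per-cell ROIs from a label-image TIFF
#'
#' The file must contain integer labels with 0 as background; one
#' [cell_roi()] is returned per distinct positive label.
#'
#' @param path single-page label TIFF.
#' @return List of [cell_roi()] objects (possibly empty).
#' @export
read_roi_labels <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(img)) img <- img[[1]]
  if (any(img != round(img)) || any(img < 0))
    stop_input("ROI label image must contain non-negative integers")
  labs <- sort(unique(img[img > 0]))
  lapply(labs, function(l) cell_roi(l, img == l, source = "manual_file"))
}

#' Write a label mask as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_labels <- function(labels, path) {
  if (any(labels != round(labels)) || any(labels < 0) ||
      max(labels) > 65535)
    stop_input("labels must be integers in 0..65535")
  tiff::writeTIFF(round(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Run manifest for provenance logging
#'
#' Records the command, all resolved parameters, content digests (MD5) of
#' the input files, the package version, the seed and a timestamp, so a
#' run can be reproduced exactly.
#'
#' @param command command or function name.
#' @param parameters named list of resolved parameter values.
#' @param inputs character vector of input file paths (hashed).
#' @param seed integer seed or `NULL`.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(command, parameters = list(),
                         inputs = character(0), seed = NULL) {
  hashes <- if (length(inputs) > 0) as.list(tools::md5sum(inputs))
            else list()
  structure(list(command = command, parameters = parameters,
                 input_hashes = hashes,
                 software_version =
                   as.character(packageVersion("secrflux")),
                 seed = seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' Write result tables and a run manifest to a directory
#'
#' Each table is written as CSV with its given column order and numbers
#' formatted to 6 significant digits; the manifest goes to
#' `manifest.json`. Existing files are never overwritten unless
#' `force = TRUE`.
#'
#' @param tables named list of data frames.
#' @param manifest a [run_manifest()].
#' @param out_dir output directory (created if missing).
#' @param force overwrite existing files.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, manifest, out_dir, force = FALSE) {
  stopifnot(is.list(tables), inherits(manifest, "run_manifest"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c(paste0(names(tables), ".csv"),
                                "manifest.json"))
  clash <- files[file.exists(files)]
  if (length(clash) > 0 && !force)
    stop_input("refusing to overwrite (use force = TRUE): ",
               paste(basename(clash), collapse = ", "))
  for (nm in names(tables)) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(files)
}
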