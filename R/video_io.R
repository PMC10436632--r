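#' Read a cine loop from a directory of grayscale images
#'
#' Loads every PNG (and, when the `tiff` package is available, TIFF)
#' image in `path` as one frame, ordered by the number embedded in the
#' file name (`f2.png` sorts before `f10.png`), falling back to
#' lexicographic order when no number is present. Color images are
#' reduced to grayscale with the luma weights (0.299, 0.587, 0.114).
#'
#' @param path directory containing at least 2 image files.
#' @param frame_interval seconds per frame.
#' @return a [frame_sequence] with `pixel_spacing = NULL`.
#' @export
read_image_directory <- function(path, frame_interval) {
  if (!dir.exists(path)) stop("not a directory: ", path, call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) < 2L) {
    stop("need at least 2 image files in ", path, " (found ",
         length(files), ")", call. = FALSE)
  }
  nums <- suppressWarnings(
    as.numeric(sub("^.*?(\\d+)\\D*$", "\\1", basename(files))))
  ord <- if (anyNA(nums)) order(basename(files)) else order(nums)
  files <- files[ord]

  frames <- lapply(files, .read_gray_image)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("images in ", path, " have mixed dimensions", call. = FALSE)
  }
  frame_sequence(frames, frame_interval, source_id = path)
}

.read_gray_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") {
    png::readPNG(file)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF frames",
           call. = FALSE)
    }
    tiff::readTIFF(file)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img * 255
}

#' Write kinematic curves and cycle annotation to disk
#'
#' Writes the curve table as CSV (columns `time_s`, `interframe_h_px`,
#' `interframe_v_px`, `cumulative_h_px`, `cumulative_v_px`,
#' `gs_percent`, plus `cumulative_h_mm`/`cumulative_v_mm` when a pixel
#' spacing is known) and a JSON sidecar (`<stem>_meta.json`) holding the
#' detected period, peak/trough indices, and the configuration used.
#'
#' @param curves a `kinematic_curves` data frame from
#'   [displacement_curves()] / [run_pipeline()].
#' @param cycles a `cycle_annotation`, or `NULL`.
#' @param path output CSV path; the sidecar replaces the extension with
#'   `_meta.json`.
#' @param pixel_spacing optional `(row_mm, col_mm)` to add mm columns.
#' @param config optional named list recorded verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, cycles = NULL, path,
                         pixel_spacing = NULL, config = NULL) {
  if (is.null(curves) || nrow(curves) == 0L) {
    stop("curves are empty; nothing to write", call. = FALSE)
  }
  tab <- data.frame(
    time_s = curves$time,
    interframe_h_px = curves$interframe_h,
    interframe_v_px = curves$interframe_v,
    cumulative_h_px = curves$cumulative_h,
    cumulative_v_px = curves$cumulative_v,
    gs_percent = curves$gs)
  if (!is.null(pixel_spacing)) {
    tab$cumulative_h_mm <- curves$cumulative_h * pixel_spacing[2]
    tab$cumulative_v_mm <- curves$cumulative_v * pixel_spacing[1]
  }
  utils::write.csv(tab, path, row.names = FALSE)

  meta <- list(
    period_s = if (!is.null(cycles)) cycles$period_T else NULL,
    peaks = if (!is.null(cycles)) cycles$peaks else NULL,
    troughs = if (!is.null(cycles)) cycles$troughs else NULL,
    source_curve = if (!is.null(cycles)) cycles$source_curve else NULL,
    config = config)
  meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
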