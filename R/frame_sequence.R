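#' Construct a frame sequence
#'
#' A `frame_sequence` is the uniform in-memory representation of an
#' ultrasound cine loop: an ordered list of grayscale frames sharing one
#' geometry, plus the time between frames. All stages of the pipeline
#' consume this container, whether the frames came from a multi-frame
#' DICOM file, a directory of images, or the synthetic phantom.
#'
#' Coordinates throughout the package are 1-based `(row, col)` with rows
#' increasing downward; "horizontal" motion is along columns and
#' "vertical" motion along rows, matching the screen orientation of a
#' B-mode display.
#'
#' @param frames list of numeric matrices with identical dimensions;
#'   intensities in `[0, 255]`.
#' @param frame_interval seconds per frame, `> 0`.
#' @param pixel_spacing optional numeric length-2 `(row_mm, col_mm)`
#'   physical pixel size in millimetres, or `NULL` when unknown.
#' @param source_id free-text provenance string.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_interval, pixel_spacing = NULL,
                           source_id = "memory") {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("a frame sequence needs at least 2 frames", call. = FALSE)
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("all frames must be matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share identical height and width", call. = FALSE)
  }
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) {
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a single positive number", call. = FALSE)
  }
  if (!is.null(pixel_spacing)) {
    stopifnot(is.numeric(pixel_spacing), length(pixel_spacing) == 2L,
              all(pixel_spacing > 0))
  }
  structure(
    list(frames = frames,
         frame_interval = as.numeric(frame_interval),
         pixel_spacing = pixel_spacing,
         source_id = as.character(source_id)),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d px, %.4g s/frame (%s)\n",
              length(x$frames), d[1], d[2], x$frame_interval, x$source_id))
  if (!is.null(x$pixel_spacing)) {
    cat(sprintf("  pixel spacing %.4g x %.4g mm\n",
                x$pixel_spacing[1], x$pixel_spacing[2]))
  }
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `frame_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$frames)
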