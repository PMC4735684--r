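# Frames and image sequences.
#
# A frame is a plain integer matrix of 8-bit intensities; rows are image rows
# (y, increasing downwards), columns are image columns (x, increasing to the
# right). All pixel coordinates exposed to the user are 0-based with (x, y)
# ordering, matching the CSV outputs.

#' Validate and coerce a frame
#'
#' A frame is an integer matrix with all intensities in `[0, 255]`. Numeric
#' matrices are rounded and coerced; anything out of range is an error, not
#' silently clipped (clipping is an explicit step of [add_noise()]).
#'
#' @param x a numeric or integer matrix.
#' @return an integer matrix of the same dimensions.
#' @export
as_frame <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a frame must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("frame dimensions must be at least 1x1", call. = FALSE)
  }
  if (anyNA(x)) stop("frame contains missing intensities", call. = FALSE)
  x <- round(x)
  if (min(x) < 0 || max(x) > 255) {
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Construct an image sequence
#'
#' Bundles an ordered list of equally sized frames with acquisition metadata.
#' Motion analysis needs at least two frames; single-frame sequences are
#' allowed so partially built objects can be inspected, and length is checked
#' again by [compute_sequence_fields()].
#'
#' @param frames list of frames (integer matrices, see [as_frame()]).
#' @param frame_rate acquisition rate in frames per second; must be positive.
#' @param pixel_size physical pixel size in micrometres per pixel, or `NULL`
#'   when unknown (speeds then stay in pixels/frame).
#' @return an object of class `image_sequence`.
#' @export
image_sequence <- function(frames, frame_rate, pixel_size = NULL) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("'frames' must be a non-empty list of frames", call. = FALSE)
  }
  frames <- lapply(frames, as_frame)
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) {
    stop(sprintf("frame %d has dimensions differing from frame 1",
                 which(!same)[1L]), call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("'frame_rate' must be a single positive number (frames/s)",
         call. = FALSE)
  }
  if (!is.null(pixel_size) &&
      (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)) {
    stop("'pixel_size' must be NULL or a single positive number (um/pixel)",
         call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         pixel_size = if (is.null(pixel_size)) NULL else as.numeric(pixel_size)),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("image_sequence: %d frame(s) of %d x %d pixels (w x h), %g fps",
              length(x$frames), d[2L], d[1L], x$frame_rate))
  if (!is.null(x$pixel_size)) cat(sprintf(", %g um/pixel", x$pixel_size))
  cat("\n")
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)

# width/height helpers (0-based coordinate convention lives at the interfaces;
# internally R matrices are 1-based).
frame_height <- function(f) nrow(f)
frame_width <- function(f) ncol(f)
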