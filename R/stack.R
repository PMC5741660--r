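#' Calibrated image stack
#'
#' A time-ordered stack of grayscale frames with spatial and temporal
#' calibration. Frames are stored as an H x W x T numeric array of
#' non-negative intensities (arbitrary camera units, typically a 12-bit
#' range).
#'
#' @param frames numeric array H x W x T, or a matrix for a single frame.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param frame_interval_s time between frames in seconds.
#' @param channel character label, e.g. "actin".
#' @return an object of class \code{calibrated_stack}.
#' @export
calibrated_stack <- function(frames, pixel_size_um, frame_interval_s = 1,
                             channel = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    wt_stop("'frames' must be an H x W x T array", "validation_error",
            field = "frames")
  if (any(!is.finite(frames)) || any(frames < 0))
    wt_stop("intensities must be finite and >= 0", "validation_error",
            field = "frames")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(frame_interval_s, "frame_interval_s")
  structure(list(frames = frames,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel = channel),
            class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calibrated_stack> %d x %d px, %d frame(s), %.4g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @export
dim.calibrated_stack <- function(x) dim(x$frames)

#' Extract one frame of a calibrated stack as a matrix
#' @param stack a \code{calibrated_stack}.
#' @param t frame index (1-based).
#' @export
get_frame <- function(stack, t) {
  stopifnot(inherits(stack, "calibrated_stack"))
  t <- check_count(t, "t")
  if (t > dim(stack$frames)[3])
    wt_stop("frame index out of range", "validation_error", field = "t")
  stack$frames[, , t]
}

#' Frame timestamps in seconds
#' @param stack a \code{calibrated_stack}.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3]) - 1) * stack$frame_interval_s
}
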