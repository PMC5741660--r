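# Intensity line scans along neurites, alignment to the wave-front
# half-maximum, and averaged multi-channel profiles.

#' Line-scan trace container
#'
#' @param arc_um strictly increasing arc positions (increasing toward the
#'   growth cone).
#' @param intensities named list of per-channel intensity vectors, all the
#'   same length as \code{arc_um}.
#' @param source_id optional identifier.
#' @export
linescan_trace <- function(arc_um, intensities, source_id = NULL) {
  if (any(diff(arc_um) <= 0))
    wt_stop("'arc_um' must be strictly increasing", "validation_error",
            field = "arc_um")
  if (!is.list(intensities) || !length(intensities))
    wt_stop("'intensities' must be a non-empty named list", "validation_error",
            field = "intensities")
  if (any(vapply(intensities, length, 1L) != length(arc_um)))
    wt_stop("all channels must have the same length as 'arc_um'",
            "validation_error", field = "intensities")
  structure(list(arc_um = arc_um, intensities = intensities,
                 source_id = source_id, alignment_offset_um = 0),
            class = "linescan_trace")
}

#' Extract a background-subtracted line scan from a frame
#'
#' Samples the (background-subtracted) intensity along a path by bilinear
#' interpolation at the stated step. Increasing arc position points toward
#' the growth cone (the path is given soma-to-GC).
#'
#' @param frame intensity matrix, or a named list of matrices (channels).
#' @param path_px two-column matrix of (row, col) pixel coordinates,
#'   soma end first.
#' @param step_um sampling step in micrometres.
#' @param pixel_size_um micrometres per pixel.
#' @param background_percentile percentile (0-100) subtracted per channel.
#' @param source_id optional identifier.
#' @return a \code{\link{linescan_trace}}.
#' @export
extract_linescan <- function(frame, path_px, step_um, pixel_size_um,
                             background_percentile = 5, source_id = NULL) {
  check_positive(step_um, "step_um"); check_positive(pixel_size_um, "pixel_size_um")
  channels <- if (is.matrix(frame)) list(intensity = frame) else frame
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  if (any(path_px[, 1] < 1 | path_px[, 1] > H | path_px[, 2] < 1 | path_px[, 2] > W))
    wt_stop("path lies outside the image", "geometry_error")
  d <- sqrt(diff(path_px[, 1])^2 + diff(path_px[, 2])^2) * pixel_size_um
  arc <- c(0, cumsum(d))
  total <- arc[length(arc)]
  s <- seq(0, by = step_um, length.out = floor(total / step_um) + 1L)
  r <- stats::approx(arc, path_px[, 1], xout = s)$y
  c_ <- stats::approx(arc, path_px[, 2], xout = s)$y
  ints <- lapply(channels, function(img) {
    bg <- stats::quantile(img, background_percentile / 100, names = FALSE)
    pmax(bilinear_sample(img, r, c_) - bg, 0)
  })
  linescan_trace(s, ints, source_id = source_id)
}

#' Arc position of the wave-front half-maximum
#'
#' Locates the profile maximum, then the interpolated crossing of
#' (baseline + peak) / 2 on the growth-cone side of it. The baseline is the
#' median of the lowest 10 percent of trace values.
#'
#' @param trace a \code{\link{linescan_trace}} (or numeric vector with
#'   \code{arc_um} supplied).
#' @param channel channel used for the front (default first).
#' @param arc_um arc positions when \code{trace} is a bare vector.
#' @param front_direction +1 if the growth cone lies toward increasing arc
#'   (default), -1 otherwise.
#' @param min_peak_factor the maximum must exceed baseline by this factor,
#'   otherwise a no-front error is signalled.
#' @return arc position of the half-maximum crossing, micrometres.
#' @export
find_front_half_max <- function(trace, channel = NULL, arc_um = NULL,
                                front_direction = 1, min_peak_factor = 1.5) {
  if (inherits(trace, "linescan_trace")) {
    y <- trace$intensities[[channel %||% 1L]]
    x <- trace$arc_um
  } else { y <- trace; x <- arc_um }
  if (is.null(x) || length(x) != length(y))
    wt_stop("arc positions missing or mismatched", "validation_error",
            field = "arc_um")
  n10 <- max(1L, floor(length(y) * 0.1))
  baseline <- stats::median(sort(y)[seq_len(n10)])
  pk <- which.max(y)
  if (max(y) <= min_peak_factor * max(baseline, 1e-12) || diff(range(y)) == 0)
    wt_stop("no wave front: trace has no clear maximum above baseline",
            "no_front_error")
  half <- (baseline + y[pk]) / 2
  idxs <- if (front_direction >= 0) pk:length(y) else pk:1
  below <- which(y[idxs] < half)
  if (!length(below))
    wt_stop("no wave front: profile never falls below half maximum on the GC side",
            "no_front_error")
  j <- below[1]
  i_hi <- idxs[j - 1L]; i_lo <- idxs[j]
  # linear interpolation between the bracketing samples
  f <- (y[i_hi] - half) / (y[i_hi] - y[i_lo])
  x[i_hi] + f * (x[i_lo] - x[i_hi])
}

#' Average line-scan traces after front half-max alignment
#'
#' Each trace is divided by its mean intensity (per channel), smoothed with a
#' moving average, shifted so its front half-maximum (on the reference
#' channel) sits at arc 0, resampled to a common grid at the finest input
#' step, and averaged with a per-position SEM.
#'
#' @param traces list of \code{\link{linescan_trace}} objects (>= 2), each
#'   with a valid front half-max on the reference channel.
#' @param reference_channel channel used for the alignment (default first).
#' @param smoothing_window moving-average window in samples (default 5).
#' @param normalize divide each trace by its per-channel mean (default TRUE).
#' @param front_direction passed to \code{\link{find_front_half_max}}.
#' @return list of class \code{aligned_profile}: \code{arc_um} (0 = wave
#'   front), per-channel \code{mean} and \code{sem} matrices (columns =
#'   channels), and \code{n}.
#' @export
average_aligned_traces <- function(traces, reference_channel = NULL,
                                   smoothing_window = 5, normalize = TRUE,
                                   front_direction = 1) {
  if (length(traces) < 2)
    wt_stop("need at least 2 traces", "insufficient_data_error")
  chans <- names(traces[[1]]$intensities)
  ref <- reference_channel %||% chans[1]
  step <- min(vapply(traces, function(tr) min(diff(tr$arc_um)), 1))

  prepped <- lapply(traces, function(tr) {
    ints <- lapply(tr$intensities, function(y) {
      if (normalize) y <- y / mean(y)
      moving_average(y, smoothing_window)
    })
    sm <- linescan_trace(tr$arc_um, ints, tr$source_id)
    off <- find_front_half_max(sm, channel = ref,
                               front_direction = front_direction)
    list(arc = tr$arc_um - off, ints = ints)
  })
  lo <- max(vapply(prepped, function(p) min(p$arc), 1))
  hi <- min(vapply(prepped, function(p) max(p$arc), 1))
  if (hi - lo < 2 * step)
    wt_stop("traces do not overlap after alignment", "coverage_error")
  grid <- seq(lo, hi, by = step)
  res <- list(arc_um = grid, n = length(traces), channels = chans)
  for (ch in chans) {
    m <- vapply(prepped, function(p)
      stats::approx(p$arc, p$ints[[ch]], xout = grid)$y, numeric(length(grid)))
    res$mean[[ch]] <- rowMeans(m)
    res$sem[[ch]] <- apply(m, 1, stats::sd) / sqrt(ncol(m))
  }
  class(res) <- "aligned_profile"
  res
}

#' Peak-to-peak offset between two channels of an averaged profile
#'
#' Positive when \code{channel_b}'s peak sits behind (at lower arc than)
#' \code{channel_a}'s, i.e. toward the soma.
#'
#' @param profile an \code{aligned_profile}.
#' @param channel_a,channel_b channel names.
#' @return offset in micrometres.
#' @export
profile_peak_offset <- function(profile, channel_a, channel_b) {
  pa <- profile$arc_um[which.max(profile$mean[[channel_a]])]
  pb <- profile$arc_um[which.max(profile$mean[[channel_b]])]
  pa - pb
}
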