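# Readers and writers shared by all modules: multi-page TIFF with a JSON
# calibration sidecar, seed/ROI annotations as JSON, trajectories as CSV.
# Pixel coordinates are 0-based (row, col) on disk and 1-based inside R.

#' Write a calibrated stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are scaled to 16-bit by a factor recorded in the sidecar
#' (together with pixel size and frame interval), so the paired reader
#' recovers them losslessly up to the 16-bit quantisation of the scale.
#'
#' @param stack a \code{\link{calibrated_stack}}.
#' @param path output .tif path; the sidecar is written at \code{path}.json.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  mx <- max(stack$frames, 1)
  scale <- 65535 / mx
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(t)
    round(stack$frames[, , t] * scale) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               intensity_scale = scale, n_frames = d[3],
               channel = stack$channel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated stack written by \code{\link{write_stack}}
#'
#' Also reads plain (multi-page) TIFFs, in which case calibration must be
#' supplied.
#'
#' @param path .tif path.
#' @param pixel_size_um,frame_interval_s used when no sidecar exists.
#' @return a \code{\link{calibrated_stack}}.
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scale <- meta$intensity_scale %||% NULL
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , t] <- if (!is.null(scale)) pg * 65535 / scale else pg
  }
  calibrated_stack(frames,
                   pixel_size_um %||% meta$pixel_size_um %||%
                     wt_stop("pixel size neither in sidecar nor supplied",
                             "validation_error", field = "pixel_size_um"),
                   frame_interval_s %||% meta$frame_interval_s %||% 1,
                   channel = meta$channel %||% NULL)
}

#' Write seed annotations as JSON (0-based pixel coordinates)
#' @param seeds list with soma_point, hillock_point, edge_point and optional
#'   wave_point, each c(row, col), 1-based as used inside R.
#' @param path output path.
#' @export
write_seeds <- function(seeds, path) {
  to0 <- function(p) if (is.null(p)) NULL else as.numeric(p) - 1
  jsonlite::write_json(list(soma_point = to0(seeds$soma_point),
                            hillock_point = to0(seeds$hillock_point),
                            edge_point = to0(seeds$edge_point),
                            wave_point = to0(seeds$wave_point)),
                       path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' Read seed annotations written by \code{\link{write_seeds}}
#' @param path JSON path.
#' @return list with 1-based c(row, col) points.
#' @export
read_seeds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  to1 <- function(p) if (is.null(p) || !length(p)) NULL else as.numeric(p) + 1
  list(soma_point = to1(raw$soma_point), hillock_point = to1(raw$hillock_point),
       edge_point = to1(raw$edge_point), wave_point = to1(raw$wave_point))
}

#' Write a trajectory as CSV
#' @param trajectory an \code{aw_trajectory}.
#' @param path output CSV path (wave tracks go to \code{path} with suffix
#'   "_tracks.csv").
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  tracks <- attr(trajectory, "wave_tracks") %||% list()
  if (length(tracks)) {
    tk <- do.call(rbind, lapply(seq_along(tracks), function(i)
      cbind(track = i, tracks[[i]])))
    utils::write.csv(tk, sub("\\.csv$", "_tracks.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a trajectory CSV written by \code{\link{write_trajectory}}
#' @param path CSV path.
#' @param pixel_size_um optional calibration to attach.
#' @export
read_trajectory <- function(path, pixel_size_um = NULL) {
  out <- utils::read.csv(path)
  tpath <- sub("\\.csv$", "_tracks.csv", path)
  tracks <- list()
  if (file.exists(tpath)) {
    tk <- utils::read.csv(tpath)
    tracks <- lapply(split(tk, tk$track), function(d) d[-1])
  }
  attr(out, "wave_tracks") <- unname(tracks)
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("aw_trajectory", "data.frame")
  out
}

#' Write ROI polygons as JSON (0-based (row, col) vertices)
#' @param rois list of \code{\link{region_of_interest}}.
#' @param path output path.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(rois, function(r)
    list(label = r$label, pixel_size_um = r$pixel_size_um,
         polygon = unname(apply(r$polygon - 1, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROI polygons written by \code{\link{write_rois}}
#' @param path JSON path.
#' @return list of \code{\link{region_of_interest}}.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, as.numeric)) + 1
    region_of_interest(poly, r$label, r$pixel_size_um)
  })
}
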