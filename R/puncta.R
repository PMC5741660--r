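# STED-scale myosin puncta detection, ROI densities with actin normalisation,
# and rear/front tendency classification.

#' Region of interest
#'
#' @param polygon two-column matrix of (row, col) pixel vertices (1-based,
#'   open ring).
#' @param label one of "AW_central_rear", "AW_central_front", "AW_peripheral",
#'   "GC_central_transition", "GC_peripheral", "neurite_proximal",
#'   "neurite_distal".
#' @param pixel_size_um micrometres per pixel (used for the area).
#' @export
region_of_interest <- function(polygon, label, pixel_size_um) {
  check_positive(pixel_size_um, "pixel_size_um")
  labels <- c("AW_central_rear", "AW_central_front", "AW_peripheral",
              "GC_central_transition", "GC_peripheral",
              "neurite_proximal", "neurite_distal")
  if (!label %in% labels)
    wt_stop(paste("unknown ROI label:", label), "validation_error",
            field = "label")
  if (!polygon_is_simple(polygon))
    wt_stop("ROI polygon is self-intersecting", "geometry_error")
  area <- polygon_area(polygon) * pixel_size_um^2
  if (area <= 0)
    wt_stop("ROI area must be positive", "validation_error", field = "polygon")
  if (label %in% c("neurite_proximal", "neurite_distal") &&
      (area < 8 || area > 12))
    wt_stop("neurite section ROIs must have an area of 8-12 um^2",
            "validation_error", field = "polygon")
  structure(list(polygon = polygon, label = label,
                 pixel_size_um = pixel_size_um, area_um2 = area),
            class = "region_of_interest")
}

#' Detect myosin puncta in a STED channel
#'
#' Background-subtracts, thresholds, labels 8-connected components, splits
#' components carrying several well-separated local intensity maxima (two
#' puncta whose suprathreshold footprints touch but whose peaks remain
#' distinct), keeps detections whose equivalent diameter lies within the
#' stated bounds, and returns intensity-weighted centroids. Two puncta closer
#' than the resolvable peak separation still merge into a single detection
#' (documented merge behaviour).
#'
#' @param image myosin channel matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param background_percentile percentile (0-100) subtracted first.
#' @param threshold absolute intensity cutoff after background subtraction;
#'   NULL uses 0.7 x the 99.9th percentile of the subtracted image (a robust
#'   stand-in for half the punctum amplitude), floored at six robust noise
#'   standard deviations (median + 6 x 1.4826 MAD) so that a scene without
#'   puncta, where the 99.9th percentile is just the noise tail, yields no
#'   detections.
#' @param min_diameter_um,max_diameter_um equivalent-diameter bounds
#'   (defaults 0.04 and 0.4 um).
#' @param min_peak_sep_px minimum separation between local maxima for a
#'   component to be split.
#' @return data.frame with columns r, c (fractional pixel centroids) and
#'   area_px.
#' @export
detect_puncta <- function(image, pixel_size_um, background_percentile = 10,
                          threshold = NULL, min_diameter_um = 0.04,
                          max_diameter_um = 0.4, min_peak_sep_px = 3) {
  check_positive(pixel_size_um, "pixel_size_um")
  bg <- stats::quantile(image, background_percentile / 100, names = FALSE)
  img <- pmax(image - bg, 0)
  thr <- threshold %||% max(0.7 * stats::quantile(img, 0.999, names = FALSE),
                            stats::median(img) + 6 * stats::mad(img))
  mask <- img > thr
  empty <- data.frame(r = numeric(0), c = numeric(0), area_px = numeric(0))
  if (!any(mask) || thr <= 0) return(empty)
  H <- nrow(img)
  lab <- label_components(mask, 8)
  n <- max(lab)
  out <- vector("list", n)
  for (b in seq_len(n)) {
    bidx <- which(lab == b)
    br <- ((bidx - 1L) %% H) + 1L; bc <- ((bidx - 1L) %/% H) + 1L
    v <- img[bidx]
    # local maxima inside the component (3x3 neighbourhood, >= 50% of the
    # component peak), deduplicated at min_peak_sep_px
    is_max <- vapply(seq_along(bidx), function(i) {
      r0 <- br[i]; c0 <- bc[i]
      nb <- img[max(1, r0 - 1):min(H, r0 + 1),
                max(1, c0 - 1):min(ncol(img), c0 + 1)]
      v[i] >= max(nb)
    }, logical(1))
    peaks <- which(is_max & v >= 0.5 * max(v))
    if (length(peaks) > 1) {
      ord <- peaks[order(-v[peaks])]
      kept <- ord[1]
      for (pk in ord[-1]) {
        if (all((br[pk] - br[kept])^2 + (bc[pk] - bc[kept])^2 >=
                min_peak_sep_px^2))
          kept <- c(kept, pk)
      }
      peaks <- kept
    } else if (!length(peaks)) peaks <- which.max(v)
    # assign pixels to the nearest peak
    assign <- if (length(peaks) == 1) rep(1L, length(bidx)) else
      apply(outer(br, br[peaks], "-")^2 + outer(bc, bc[peaks], "-")^2,
            1, which.min)
    subs <- lapply(seq_along(peaks), function(k) {
      sel <- assign == k
      a <- sum(sel)
      # The minimum-diameter gate uses the FWHM footprint around the peak
      # (pixels at or above half the peak in a local window), which does not
      # shrink when the global threshold sits above half-amplitude; the
      # maximum gate uses the suprathreshold area.
      w <- v[sel]
      pk <- which.max(w)
      pr <- br[sel][pk]; pc <- bc[sel][pk]
      nb <- img[max(1, pr - 4):min(H, pr + 4),
                max(1, pc - 4):min(ncol(img), pc + 4)]
      a_fwhm <- sum(nb >= 0.5 * max(w))
      diam_lo <- 2 * sqrt(max(a, a_fwhm) / pi) * pixel_size_um
      diam_hi <- 2 * sqrt(a / pi) * pixel_size_um
      if (diam_lo < min_diameter_um || diam_hi > max_diameter_um) return(NULL)
      data.frame(r = sum(br[sel] * w) / sum(w),
                 c = sum(bc[sel] * w) / sum(w), area_px = a)
    })
    out[[b]] <- do.call(rbind, subs)
  }
  do.call(rbind, out) %||% empty
}

#' Puncta density in a region of interest
#'
#' Counts centroids strictly inside the polygon (even-odd rule), divides by
#' the ROI area, and optionally normalises by the ROI's relative actin
#' intensity: density / (ROI actin mean / scene-wise maximum ROI actin mean),
#' so a region at the actin maximum is unchanged.
#'
#' @param centroids data.frame with r, c (from \code{\link{detect_puncta}}).
#' @param roi a \code{\link{region_of_interest}}.
#' @param actin_image actin channel (needed when normalising).
#' @param normalize compute the actin-normalised density.
#' @param scene_max_actin_mean the maximum ROI actin mean over the scene's
#'   ROI set; NULL uses this ROI's own mean (normalised density = density).
#' @return one-row data.frame of class \code{puncta_record}: label, count,
#'   area_um2, density_per_um2, actin_mean, normalized_density.
#' @export
roi_density <- function(centroids, roi, actin_image = NULL, normalize = FALSE,
                        scene_max_actin_mean = NULL) {
  stopifnot(inherits(roi, "region_of_interest"))
  inside <- if (nrow(centroids))
    point_in_polygon(centroids$c, centroids$r,
                     roi$polygon[, c(2, 1), drop = FALSE]) else logical(0)
  count <- sum(inside)
  density <- count / roi$area_um2
  actin_mean <- NA_real_; norm_density <- NA_real_
  if (!is.null(actin_image)) {
    # pixel centres inside the polygon, evaluated on the bounding-box crop
    r0 <- max(1L, floor(min(roi$polygon[, 1])))
    r1 <- min(nrow(actin_image), ceiling(max(roi$polygon[, 1])))
    c0 <- max(1L, floor(min(roi$polygon[, 2])))
    c1 <- min(ncol(actin_image), ceiling(max(roi$polygon[, 2])))
    gr <- expand.grid(r = r0:r1, c = c0:c1)
    inpoly <- point_in_polygon(gr$c, gr$r, roi$polygon[, c(2, 1), drop = FALSE])
    actin_mean <- mean(actin_image[r0:r1, c0:c1][inpoly])
  }
  if (normalize) {
    if (is.null(actin_image))
      wt_stop("normalisation needs the actin channel", "validation_error",
              field = "actin_image")
    if (!is.finite(actin_mean) || actin_mean <= 0)
      wt_stop("zero actin mean: normalised density undefined",
              "normalization_error")
    ref <- scene_max_actin_mean %||% actin_mean
    norm_density <- density / (actin_mean / ref)
  }
  out <- data.frame(label = roi$label, count = count, area_um2 = roi$area_um2,
                    density_per_um2 = density, actin_mean = actin_mean,
                    normalized_density = norm_density)
  class(out) <- c("puncta_record", "data.frame")
  out
}

#' Puncta densities for a whole ROI set
#'
#' Convenience wrapper: computes per-ROI records with the scene-wise maximum
#' actin mean as the normalisation reference.
#'
#' @param centroids from \code{\link{detect_puncta}}.
#' @param rois list of \code{\link{region_of_interest}}.
#' @param actin_image actin channel matrix (or NULL to skip normalisation).
#' @return data.frame with one row per ROI.
#' @export
roi_density_table <- function(centroids, rois, actin_image = NULL) {
  if (is.null(actin_image)) {
    recs <- lapply(rois, function(r) roi_density(centroids, r))
    return(do.call(rbind, recs))
  }
  means <- vapply(rois, function(r)
    roi_density(centroids, r, actin_image)$actin_mean, 1)
  ref <- max(means)
  recs <- lapply(rois, function(r)
    roi_density(centroids, r, actin_image, normalize = TRUE,
                scene_max_actin_mean = ref))
  do.call(rbind, recs)
}

#' Classify a rear-to-front (or proximal-to-distal) density tendency
#'
#' Relative change = (b - a) / a; an absolute change below the stability band
#' (12 percent) is "stable", otherwise the sign decides
#' "increase" / "decrease".
#'
#' @param density_a reference density (> 0), e.g. rear or proximal.
#' @param density_b comparison density, e.g. front or distal.
#' @param stable_band half-width of the stable band as a fraction
#'   (default 0.12).
#' @return "increase", "decrease" or "stable"; NA with attribute
#'   \code{reason = "undefined-change"} when density_a is 0.
#' @export
classify_tendency <- function(density_a, density_b, stable_band = 0.12) {
  if (!is.finite(density_a) || density_a == 0) {
    out <- NA_character_; attr(out, "reason") <- "undefined-change"
    return(out)
  }
  change <- (density_b - density_a) / density_a
  if (abs(change) < stable_band) "stable"
  else if (change > 0) "increase"
  else "decrease"
}
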