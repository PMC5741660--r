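# Area morphometry of actin waves and growth cones, and the growth-cone
# response (fold change, fractional loss) around wave arrival.

#' Area time course of a seeded region
#'
#' Per sampled frame the region is segmented by thresholding a window around
#' the seed and taking the connected component containing it; its area is the
#' pixel count times pixel_size^2. The seed is propagated as the previous
#' frame's region centroid. Replaces manual outlining with a reproducible
#' seeded segmentation.
#'
#' @param stack a \code{\link{calibrated_stack}}.
#' @param seed c(row, col) on the region at the first sampled frame.
#' @param frames frame indices to sample (default all).
#' @param threshold_policy "otsu" (Otsu's threshold inside the window) or
#'   "fraction" (threshold = background + threshold_fraction x (window max -
#'   background)).
#' @param threshold_fraction used by the "fraction" policy.
#' @param window_px half-size of the square analysis window around the seed.
#' @param label "GC" or "AW" (annotation only).
#' @return data.frame of class \code{area_series}: frame, time_s, area_um2,
#'   lost (flag for frames where the seed left the segmented foreground).
#' @export
region_area_timecourse <- function(stack, seed, frames = NULL,
                                   threshold_policy = c("otsu", "fraction"),
                                   threshold_fraction = 0.5,
                                   window_px = 40, label = "GC") {
  stopifnot(inherits(stack, "calibrated_stack"))
  threshold_policy <- match.arg(threshold_policy)
  d <- dim(stack$frames)
  frames <- frames %||% seq_len(d[3])
  px2 <- stack$pixel_size_um^2
  times <- frame_times(stack)
  seed <- as.numeric(seed)
  out <- data.frame(frame = frames, time_s = times[frames],
                    area_um2 = NA_real_, lost = FALSE)
  for (k in seq_along(frames)) {
    img <- stack$frames[, , frames[k]]
    r0 <- max(1, round(seed[1]) - window_px); r1 <- min(d[1], round(seed[1]) + window_px)
    c0 <- max(1, round(seed[2]) - window_px); c1 <- min(d[2], round(seed[2]) + window_px)
    win <- img[r0:r1, c0:c1]
    bg <- stats::quantile(win, 0.05, names = FALSE)
    thr <- if (threshold_policy == "otsu") {
      rng <- range(win)
      if (diff(rng) <= 0) rng[2] + 1 else
        EBImage::otsu(EBImage::Image((win - rng[1]) / diff(rng))) * diff(rng) + rng[1]
    } else if (max(win) <= bg) max(win) + 1 else
      bg + threshold_fraction * (max(win) - bg)
    mask <- win >= thr
    sr <- round(seed[1]) - r0 + 1L; sc <- round(seed[2]) - c0 + 1L
    if (!mask[sr, sc]) {
      # tolerate 1-px jitter of the propagated seed
      nb <- nearest_fg(mask, c(sr, sc), radius = 2)
      if (is.na(nb)) { out$lost[k] <- TRUE; out$area_um2[k] <- 0; next }
      sr <- (nb - 1L) %% nrow(mask) + 1L; sc <- (nb - 1L) %/% nrow(mask) + 1L
    }
    lab <- label_components(mask, 8)
    region <- lab == lab[sr, sc]
    out$area_um2[k] <- sum(region) * px2
    rr <- row(region)[region]; cc <- col(region)[region]
    seed <- c(mean(rr) + r0 - 1, mean(cc) + c0 - 1)
  }
  attr(out, "label") <- label
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  class(out) <- c("area_series", "data.frame")
  out
}

#' Growth-cone response to wave arrival
#'
#' For each wave arrival: fold change = mean area over \code{window_min}
#' minutes after arrival divided by the mean over an equal window before;
#' percent loss = (post-arrival peak - area at \code{loss_at_min} minutes
#' after the peak) / peak x 100.
#'
#' @param areas an \code{area_series} (or data.frame with time_s, area_um2).
#' @param arrival_times_s wave merge times in seconds.
#' @param window_min averaging window, minutes (default 5, the lower end of
#'   the 5-10 min sampling used after merging).
#' @param loss_at_min delay at which the loss is evaluated (default 45 min,
#'   the middle of the 30-60 min range).
#' @return data.frame: arrival_time_s, fold_change, pct_loss, usable (FALSE
#'   when a pre/post window is missing).
#' @export
gc_wave_response <- function(areas, arrival_times_s, window_min = 5,
                             loss_at_min = 45) {
  t <- areas$time_s; a <- areas$area_um2
  # frames where the seeded region was lost carry no area information
  if (!is.null(areas$lost)) a[areas$lost] <- NA_real_
  out <- data.frame(arrival_time_s = arrival_times_s,
                    fold_change = NA_real_, pct_loss = NA_real_,
                    usable = FALSE)
  for (i in seq_along(arrival_times_s)) {
    t0 <- arrival_times_s[i]
    w <- window_min * 60
    pre <- is.finite(a) & t >= t0 - w & t < t0
    post <- is.finite(a) & t >= t0 & t < t0 + w
    if (!any(pre) || !any(post)) next
    fold <- mean(a[post]) / mean(a[pre])
    after <- is.finite(a) & t >= t0
    peak_idx <- which(after)[which.max(a[after])]
    peak_t <- t[peak_idx]; peak <- a[peak_idx]
    t_loss <- peak_t + loss_at_min * 60
    if (max(t) < t_loss) {
      out$fold_change[i] <- fold
      next
    }
    a_loss <- stats::approx(t[is.finite(a)], a[is.finite(a)], xout = t_loss)$y
    out$fold_change[i] <- fold
    out$pct_loss[i] <- (peak - a_loss) / peak * 100
    out$usable[i] <- TRUE
  }
  out
}
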