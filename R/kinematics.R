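# Wave velocity and frequency, pulling-event detection, elongation statistics
# and the windowed frequency-vs-tip-velocity time course.

#' Build per-wave events from a trajectory
#'
#' Converts the per-wave tracks attached to an \code{aw_trajectory} into
#' wave-event records: distance covered, duration, mean velocity and whether
#' the wave reached the tip (within the merge tolerance).
#'
#' @param trajectory an \code{aw_trajectory} (from
#'   \code{\link{track_trajectory}} or \code{\link{truth_trajectory}}).
#' @param merge_tolerance_um a wave whose last arc position is within this
#'   tolerance of the concurrent neurite length counts as completed. An extra
#'   slack of one frame of free growth is allowed because the length is
#'   sampled at frame pitch.
#' @param min_frames tracks observed on fewer frames are dropped (spurious
#'   single-frame detections).
#' @return data.frame of class \code{wave_events}: one row per wave with
#'   columns start_frame, end_frame, start_time_s, end_time_s, distance_um,
#'   duration_min, velocity_um_min, completed.
#' @export
wave_events <- function(trajectory, merge_tolerance_um = NULL, min_frames = 3) {
  stopifnot(inherits(trajectory, "aw_trajectory"))
  tol <- merge_tolerance_um %||% attr(trajectory, "merge_tolerance_um") %||% 3
  tracks <- attr(trajectory, "wave_tracks") %||% list()
  dt_s <- if (nrow(trajectory) > 1) diff(trajectory$time_s[1:2]) else 0
  gcx <- attr(trajectory, "gc_exclude_um") %||% 0
  # frame-pitch sampling slack plus the tip-side candidate exclusion band
  slack <- tol + gcx + 3 * dt_s / 60
  rows <- lapply(tracks, function(tk) {
    if (nrow(tk) < min_frames) return(NULL)
    nlast <- nrow(tk)
    L_last <- tk$L_um[nlast]
    data.frame(
      start_frame = tk$frame[1], end_frame = tk$frame[nlast],
      start_time_s = tk$time_s[1], end_time_s = tk$time_s[nlast],
      distance_um = tk$s_um[nlast] - tk$s_um[1],
      duration_min = (tk$time_s[nlast] - tk$time_s[1]) / 60,
      velocity_um_min = wave_velocity(tk$time_s, tk$s_um),
      completed = is.finite(L_last) && tk$s_um[nlast] >= L_last - slack
    )
  })
  ev <- do.call(rbind, rows) %||%
    data.frame(start_frame = integer(0), end_frame = integer(0),
               start_time_s = numeric(0), end_time_s = numeric(0),
               distance_um = numeric(0), duration_min = numeric(0),
               velocity_um_min = numeric(0), completed = logical(0))
  class(ev) <- c("wave_events", "data.frame")
  ev
}

#' Mean wave velocity of one transit
#'
#' Distance covered divided by time taken: (s_last - s_first) /
#' (t_last - t_first), in um/min. Negative (retrograde) velocities are
#' allowed and flagged with a warning.
#'
#' @param time_s times in seconds (>= 2 wave-present samples).
#' @param s_um arc positions in micrometres (NA samples are dropped).
#' @return velocity in um/min.
#' @export
wave_velocity <- function(time_s, s_um) {
  ok <- is.finite(time_s) & is.finite(s_um)
  time_s <- time_s[ok]; s_um <- s_um[ok]
  if (length(s_um) < 2)
    wt_stop("need at least 2 wave-present samples", "insufficient_data_error")
  v <- (s_um[length(s_um)] - s_um[1]) / ((time_s[length(time_s)] - time_s[1]) / 60)
  if (is.finite(v) && v < 0) warning("retrograde wave (negative velocity)")
  v
}

#' Length-normalised transit rate of a completed wave
#'
#' (1 / transit time) x (distance covered / neurite length), in 1/min. This
#' is the time a wave takes to reach the tip normalised by the neurite
#' length; it is reported alongside, and never mixed with, the plain
#' distance-over-time velocity.
#'
#' @param event one row of a \code{wave_events} table (or a list with
#'   \code{distance_um}, \code{duration_min}, \code{completed}).
#' @param L_um neurite length in micrometres (> 0).
#' @return rate in 1/min, or NA with attribute \code{reason = "incomplete"}
#'   for waves that never reached the tip.
#' @export
normalized_transit_rate <- function(event, L_um) {
  check_positive(L_um, "L_um")
  if (!isTRUE(event$completed)) {
    out <- NA_real_; attr(out, "reason") <- "incomplete"
    return(out)
  }
  (1 / event$duration_min) * (event$distance_um / L_um)
}

#' Wave frequency in waves per hour
#'
#' @param events a \code{wave_events} table.
#' @param span_h observation span in hours (> 0).
#' @param complete_only count only waves that reached the tip.
#' @return waves/hour.
#' @export
wave_frequency <- function(events, span_h, complete_only = FALSE) {
  check_positive(span_h, "span_h")
  n <- if (complete_only) sum(events$completed) else nrow(events)
  n / span_h
}

#' Detect growth-cone pulling events
#'
#' A pulling event is a sustained decrease of the neurite length L(t) of at
#' least \code{min_amplitude_um} that begins while a wave is within
#' \code{approach_window_um} of the tip and ends at the merge (the local
#' minimum of L). Reports the onset time and the retraction amplitude.
#'
#' @param trajectory an \code{aw_trajectory} with aligned L(t) and s(t).
#' @param min_amplitude_um minimum retraction amplitude to report.
#' @param approach_window_um wave-to-tip gap defining "approaching".
#' @param rise_tol_um small upward jitter of L(t) tolerated inside one
#'   retraction run (tracking noise at pixel scale).
#' @param wave_jump_split_um a retraction run is cut where the tracked wave
#'   arc position falls back by more than this (the leading wave merged and a
#'   trailing wave took over), so back-to-back retractions driven by
#'   successive waves are reported as separate events.
#' @return data.frame with columns onset_time_s, end_time_s, amplitude_um.
#' @export
detect_pulling_events <- function(trajectory, min_amplitude_um = 5,
                                  approach_window_um = 20, rise_tol_um = 1,
                                  wave_jump_split_um = 5) {
  stopifnot(inherits(trajectory, "aw_trajectory"))
  ok <- is.finite(trajectory$L_um)   # tracking gaps are skipped over
  L <- trajectory$L_um[ok]; s <- trajectory$s_um[ok]
  t <- trajectory$time_s[ok]
  n <- length(L)
  events <- data.frame(onset_time_s = numeric(0), end_time_s = numeric(0),
                       amplitude_um = numeric(0))
  i <- 1L
  while (i < n) {
    if (is.finite(L[i]) && is.finite(L[i + 1]) && L[i + 1] < L[i]) {
      # candidate retraction run [i, j]: L decreasing (allowing NA skips),
      # cut at the merge (wave reaches the tip)
      j <- i + 1L
      while (j < n && is.finite(L[j + 1]) && L[j + 1] <= L[j] + rise_tol_um) {
        handover <- is.finite(s[j]) && is.finite(s[j + 1]) &&
          s[j + 1] < s[j] - wave_jump_split_um
        if (handover) break
        j <- j + 1L
      }
      amp <- L[i] - min(L[i:j], na.rm = TRUE)
      gap <- L[i] - s[i]
      approaching <- is.finite(gap) && gap >= 0 && gap <= approach_window_um
      # the wave may enter the window one frame into the retraction
      if (!approaching && i + 1 <= j) {
        gap2 <- L[i + 1] - s[i + 1]
        approaching <- is.finite(gap2) && gap2 >= 0 && gap2 <= approach_window_um
      }
      if (amp >= min_amplitude_um && approaching)
        events <- rbind(events, data.frame(onset_time_s = t[i],
                                           end_time_s = t[j],
                                           amplitude_um = amp))
      i <- j
    } else i <- i + 1L
  }
  events
}

#' Net elongation versus wave count across a cohort
#'
#' For each neurite, net elongation = L(T) - L(0) and the number of wave
#' events; across the cohort a Spearman rank correlation with two-sided p
#' value is reported.
#'
#' @param trajectories list of \code{aw_trajectory} objects.
#' @param min_frames passed to \code{\link{wave_events}}.
#' @return list with \code{table} (neurite, elongation_um, wave_count),
#'   \code{rho}, \code{p_value}; rho/p are NA with a flag when the
#'   correlation is undefined (all elongations identical).
#' @export
elongation_vs_wave_count <- function(trajectories, min_frames = 3) {
  if (length(trajectories) < 3)
    wt_stop("need at least 3 neurites for the correlation",
            "insufficient_data_error")
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    Ls <- tr$L_um[is.finite(tr$L_um)]
    ev <- wave_events(tr, min_frames = min_frames)
    data.frame(neurite = i,
               elongation_um = Ls[length(Ls)] - Ls[1],
               wave_count = nrow(ev))
  })
  tab <- do.call(rbind, rows)
  if (stats::sd(tab$elongation_um) == 0 || stats::sd(tab$wave_count) == 0)
    return(list(table = tab, rho = NA_real_, p_value = NA_real_,
                undefined = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(tab$wave_count, tab$elongation_um, method = "spearman",
                    alternative = "two.sided"))
  list(table = tab, rho = unname(ct$estimate), p_value = ct$p.value,
       undefined = FALSE)
}

#' Windowed wave frequency and tip velocity time course
#'
#' Splits the trajectory into consecutive non-overlapping windows; per window
#' the tip velocity is (Delta L)/(Delta t) and the frequency is the number of
#' wave events begun in the window, scaled to waves/hour. Their Pearson
#' correlation quantifies the frequency-velocity antagonism.
#'
#' @param trajectory an \code{aw_trajectory}.
#' @param window_min window length in minutes (default 60).
#' @param min_frames passed to \code{\link{wave_events}}.
#' @return list with \code{series} (window_start_min, frequency_per_h,
#'   velocity_um_min) and \code{correlation} (NA with \code{undefined = TRUE}
#'   if either series has zero variance).
#' @export
frequency_velocity_timecourse <- function(trajectory, window_min = 60,
                                          min_frames = 3) {
  stopifnot(inherits(trajectory, "aw_trajectory"))
  t_min <- trajectory$time_s / 60
  span <- max(t_min) - min(t_min)
  if (span < 2 * window_min)
    wt_stop("trajectory must span at least two windows",
            "insufficient_data_error")
  ev <- wave_events(trajectory, min_frames = min_frames)
  breaks <- seq(min(t_min), max(t_min), by = window_min)
  if (breaks[length(breaks)] < max(t_min)) breaks <- c(breaks, max(t_min))
  nw <- length(breaks) - 1L
  freq <- numeric(nw); vel <- numeric(nw)
  for (k in seq_len(nw)) {
    in_w <- t_min >= breaks[k] & t_min <= breaks[k + 1]
    tt <- t_min[in_w]; LL <- trajectory$L_um[in_w]
    ok <- is.finite(LL)
    vel[k] <- if (sum(ok) >= 2)
      (LL[ok][sum(ok)] - LL[ok][1]) / (tt[ok][sum(ok)] - tt[ok][1]) else NA
    starts <- ev$start_time_s / 60
    freq[k] <- sum(starts >= breaks[k] & starts < breaks[k + 1]) /
      ((breaks[k + 1] - breaks[k]) / 60)
  }
  series <- data.frame(window_start_min = breaks[-length(breaks)],
                       frequency_per_h = freq, velocity_um_min = vel)
  ok <- is.finite(freq) & is.finite(vel)
  if (sum(ok) < 3 || stats::sd(freq[ok]) == 0 || stats::sd(vel[ok]) == 0)
    return(list(series = series, correlation = NA_real_, undefined = TRUE))
  list(series = series,
       correlation = stats::cor(freq[ok], vel[ok], method = "pearson"),
       undefined = FALSE)
}

#' Kinematics summary of one trajectory
#'
#' @param trajectory an \code{aw_trajectory}.
#' @param complete_only count only tip-reaching waves in the frequency.
#' @return list of class \code{kinematics_summary}.
#' @export
summarize_kinematics <- function(trajectory, complete_only = FALSE) {
  ev <- wave_events(trajectory)
  span_h <- (max(trajectory$time_s) - min(trajectory$time_s)) / 3600
  Ls <- trajectory$L_um[is.finite(trajectory$L_um)]
  v <- ev$velocity_um_min
  pulls <- detect_pulling_events(trajectory)
  structure(list(
    n_waves = nrow(ev),
    frequency_per_h = if (span_h > 0) wave_frequency(ev, span_h, complete_only) else NA,
    velocity_mean = if (length(v)) mean(v) else NA_real_,
    velocity_sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
    net_elongation_um = if (length(Ls)) Ls[length(Ls)] - Ls[1] else NA_real_,
    pulling_events = pulls,
    events = ev
  ), class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("<kinematics_summary> %d wave(s), %.2f /h, velocity %.2f +/- %.2f um/min, net elongation %.1f um, %d pulling event(s)\n",
              x$n_waves, x$frequency_per_h, x$velocity_mean,
              x$velocity_sem %||% NA, x$net_elongation_um,
              nrow(x$pulling_events)))
  invisible(x)
}
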