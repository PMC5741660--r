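# Synthetic time-lapse generator: a LifeAct-style neurite movie with a soma
# blob, a curvilinear neurite, travelling growth-cone-like actin waves,
# growth-cone retraction/growth cycles, and shot + read noise. Every frame is
# backed by an exact ground-truth ledger so recovery can be tested.

#' Parameters for the synthetic neurite movie
#'
#' Defaults reproduce the regime reported for rat hippocampal neurons imaged
#' at low magnification: waves incepted as a Poisson process at 2.5 per hour,
#' per-wave speeds drawn from N(2.2, 0.4^2) um/min truncated above zero, a
#' 15 um growth-cone retraction as a wave approaches within 20 um of the tip,
#' a two-fold growth-cone area increase on merge, and tip elongation at
#' 2.5 um/min in wave-free epochs versus 0.5 um/min while a wave travels the
#' neurite.
#'
#' @param preset "paper-regime-20x" (default; 0.65 um/px, 2 min frames) or
#'   "paper-regime-40x" (0.16 um/px, 10 s frames, smaller field).
#' @param duration_min movie duration in minutes.
#' @param frame_interval_s time between frames in seconds.
#' @param pixel_size_um pixel size, um/pixel.
#' @param image_shape c(rows, cols) in pixels.
#' @param neurite_backbone matrix of (row_um, col_um) control points of the
#'   backbone curve starting at the soma centre; NULL builds a gently
#'   undulating default spanning the field of view.
#' @param initial_length_um neurite length at frame 0 (arc from soma centroid).
#' @param wave_rate_per_h Poisson inception rate, waves/hour.
#' @param wave_times_min optional explicit inception times (minutes),
#'   overriding the Poisson draw (useful for deterministic scenarios).
#' @param wave_speed_mean_um_min,wave_speed_sd_um_min per-wave anterograde
#'   speed draw, truncated > 0, held constant during transit.
#' @param wave_sigma_um spatial half-extent (Gaussian sigma) of the wave bump
#'   along the neurite.
#' @param wave_flare lateral widening factor at the bump centre (growth-cone
#'   like flare): lateral sigma = neurite_sigma_um * (1 + wave_flare * g).
#' @param gc_retraction_um retraction amplitude as a wave approaches the tip.
#' @param gc_area_fold_on_merge fold increase of the GC area at merge.
#' @param gc_area_um2 baseline growth-cone area.
#' @param gc_area_max_um2 geometric cap on the GC area (lamellipodia cannot
#'   grow without bound when several waves merge in quick succession);
#'   NULL = 3 x baseline.
#' @param gc_area_halflife_min after a merge the GC area decays from its peak
#'   with this half-life (so 50\% of the peak is lost after one half-life).
#' @param approach_distance_um gap at which an incoming wave triggers the
#'   retraction.
#' @param merge_tolerance_um a wave whose final arc position is within this
#'   tolerance of the tip counts as having reached it.
#' @param growth_speed_free_um_min,growth_speed_waves_um_min tip elongation
#'   speed without/with waves on the neurite.
#' @param soma_sigma_um Gaussian sigma of the soma blob.
#' @param hillock_arc_um arc position of the neurite hillock seed (edge of the
#'   soma).
#' @param neurite_sigma_um lateral Gaussian sigma of the neurite tube.
#' @param background_level,amplitude,read_noise_sd intensity units (12-bit
#'   range); amplitude is the wave bump peak, the soma renders at 0.8x, the
#'   GC at 0.9x and the shaft at 0.25x of it.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @param ... field overrides applied on top of the preset.
#' @return a validated object of class \code{sim_movie_params}.
#' @export
sim_movie_params <- function(preset = c("paper-regime-20x", "paper-regime-40x"),
                             ...) {
  preset <- match.arg(preset)
  p <- list(
    duration_min = 120,
    frame_interval_s = 120,
    pixel_size_um = 0.65,
    image_shape = c(96L, 224L),
    neurite_backbone = NULL,
    initial_length_um = 45,
    wave_rate_per_h = 2.5,
    wave_times_min = NULL,
    wave_speed_mean_um_min = 2.2,
    wave_speed_sd_um_min = 0.4,
    wave_sigma_um = 3,
    wave_flare = 1.5,
    gc_retraction_um = 15,
    gc_area_fold_on_merge = 2,
    gc_area_um2 = 50,
    gc_area_max_um2 = NULL,
    gc_area_halflife_min = 45,
    approach_distance_um = 20,
    merge_tolerance_um = 3,
    growth_speed_free_um_min = 2.5,
    growth_speed_waves_um_min = 0.5,
    soma_sigma_um = 5,
    hillock_arc_um = 8,
    neurite_sigma_um = 0.8,
    background_level = 100,
    amplitude = 400,
    read_noise_sd = 5,
    rng_seed = 1L
  )
  if (preset == "paper-regime-40x") {
    p$pixel_size_um <- 0.16
    p$frame_interval_s <- 10
    p$image_shape <- c(192L, 448L)
    p$duration_min <- 30
    p$initial_length_um <- 40
    p$soma_sigma_um <- 3
    p$hillock_arc_um <- 5
    p$gc_area_um2 <- 50
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    wt_stop(paste("unknown parameter(s):", paste(unknown, collapse = ", ")),
            "validation_error", field = unknown[1])
  p[names(over)] <- over
  p$preset <- preset
  class(p) <- "sim_movie_params"
  validate_sim_movie_params(p)
}

validate_sim_movie_params <- function(p) {
  for (f in c("duration_min", "frame_interval_s", "pixel_size_um",
              "initial_length_um", "wave_rate_per_h" = NA, "wave_speed_mean_um_min",
              "wave_speed_sd_um_min", "wave_sigma_um", "gc_retraction_um",
              "gc_area_fold_on_merge", "gc_area_um2", "gc_area_halflife_min",
              "approach_distance_um", "merge_tolerance_um",
              "growth_speed_free_um_min", "growth_speed_waves_um_min",
              "soma_sigma_um", "hillock_arc_um", "neurite_sigma_um",
              "amplitude"))
    if (!is.na(f)) check_positive(p[[f]], f)
  check_nonneg(p$wave_rate_per_h, "wave_rate_per_h")
  check_nonneg(p$background_level, "background_level")
  check_nonneg(p$read_noise_sd, "read_noise_sd")
  if (p$approach_distance_um <= p$gc_retraction_um)
    wt_stop("'approach_distance_um' must exceed 'gc_retraction_um'",
            "validation_error", field = "approach_distance_um")
  p$gc_area_max_um2 <- p$gc_area_max_um2 %||% (3 * p$gc_area_um2)
  if (p$gc_area_max_um2 < p$gc_area_um2)
    wt_stop("'gc_area_max_um2' must be >= 'gc_area_um2'", "validation_error",
            field = "gc_area_max_um2")
  n_frames <- floor(p$duration_min * 60 / p$frame_interval_s) + 1L
  if (n_frames < 2L)
    wt_stop("duration/frame_interval must give at least 2 frames",
            "validation_error", field = "duration_min")
  if (length(p$image_shape) != 2L || any(p$image_shape < 32))
    wt_stop("'image_shape' must be c(rows, cols), each >= 32",
            "validation_error", field = "image_shape")
  bb <- p$neurite_backbone %||% default_backbone(p)
  fine <- backbone_resample(bb, step_um = 0.25)
  if (max(fine$arc) < 20)
    wt_stop("backbone length must be >= 20 um", "validation_error",
            field = "neurite_backbone")
  if (p$initial_length_um > max(fine$arc))
    wt_stop("'initial_length_um' exceeds the backbone length",
            "validation_error", field = "initial_length_um")
  margin_um <- max(3 * p$neurite_sigma_um * (1 + p$wave_flare),
                   sqrt(p$gc_area_max_um2 / pi) + 1)
  lim_r <- p$image_shape[1] * p$pixel_size_um
  lim_c <- p$image_shape[2] * p$pixel_size_um
  if (any(fine$r < margin_um) || any(fine$r > lim_r - margin_um) ||
      any(fine$c < margin_um) || any(fine$c > lim_c - margin_um))
    wt_stop("backbone plus wave extent does not fit in the image",
            "geometry_error", field = "neurite_backbone")
  p$neurite_backbone <- bb
  p
}

# Gently undulating left-to-right backbone through the field of view,
# starting at the soma centre.
default_backbone <- function(p) {
  H_um <- p$image_shape[1] * p$pixel_size_um
  W_um <- p$image_shape[2] * p$pixel_size_um
  margin_um <- max(3 * p$neurite_sigma_um * (1 + p$wave_flare),
                   sqrt((p$gc_area_max_um2 %||% (3 * p$gc_area_um2)) / pi) + 1) + 1
  c0 <- margin_um + 2
  c1 <- W_um - margin_um
  r0 <- H_um / 2
  amp <- max(0, min(4, (H_um / 2 - margin_um) * 0.5))
  cs <- seq(c0, c1, length.out = 24)
  rs <- r0 + amp * sin((cs - c0) / (c1 - c0) * 2.2 * pi)
  cbind(r = rs, c = cs)
}

# Resample a control polyline with a natural spline at ~step_um spacing and
# return fine samples with cumulative arc length.
backbone_resample <- function(ctrl, step_um = 0.25) {
  d <- sqrt(diff(ctrl[, 1])^2 + diff(ctrl[, 2])^2)
  tt <- c(0, cumsum(d))
  n_fine <- max(64L, ceiling(tt[length(tt)] / (step_um * 0.8)))
  ts <- seq(0, tt[length(tt)], length.out = n_fine)
  r <- stats::spline(tt, ctrl[, 1], xout = ts)$y
  c_ <- stats::spline(tt, ctrl[, 2], xout = ts)$y
  arc <- c(0, cumsum(sqrt(diff(r)^2 + diff(c_)^2)))
  list(r = r, c = c_, arc = arc)
}

# Position (row_um, col_um) on the fine backbone at given arc positions.
backbone_at <- function(fine, arc) {
  arc <- pmin(pmax(arc, 0), max(fine$arc))
  cbind(r = stats::approx(fine$arc, fine$r, xout = arc)$y,
        c = stats::approx(fine$arc, fine$c, xout = arc)$y)
}

#' Simulate a neurite movie with travelling actin waves
#'
#' Runs the wave/tip dynamics at a fine sub-frame time step, records exact
#' per-frame ground truth, and (optionally) renders the scene with Poisson
#' shot noise plus Gaussian read noise clipped to a 12-bit range.
#'
#' @param params a \code{sim_movie_params} object.
#' @param render if FALSE, skip rendering (the ground truth is identical and
#'   much cheaper to produce; useful for large cohorts).
#' @return list of class \code{aw_simulation} with elements \code{stack}
#'   (a \code{\link{calibrated_stack}}, or NULL when render = FALSE) and
#'   \code{truth} (class \code{aw_ground_truth}: per-frame neurite length,
#'   GC area, wave arc positions, wave records, seed annotations, backbone).
#' @export
simulate_movie <- function(params, render = TRUE) {
  stopifnot(inherits(params, "sim_movie_params"))
  p <- validate_sim_movie_params(params)
  set.seed(p$rng_seed)

  fine <- backbone_resample(p$neurite_backbone)
  arc_max <- max(fine$arc)
  dt_frame <- p$frame_interval_s / 60           # minutes
  n_frames <- floor(p$duration_min / dt_frame) + 1L
  t_frames <- (seq_len(n_frames) - 1L) * dt_frame

  # --- wave inception times and speeds (all randomness before rendering) ---
  if (!is.null(p$wave_times_min)) {
    t0 <- sort(p$wave_times_min)
  } else {
    n_w <- stats::rpois(1L, p$wave_rate_per_h * p$duration_min / 60)
    t0 <- sort(stats::runif(n_w, 0, p$duration_min))
  }
  n_w <- length(t0)
  speeds <- numeric(n_w)
  for (i in seq_len(n_w)) {
    v <- stats::rnorm(1L, p$wave_speed_mean_um_min, p$wave_speed_sd_um_min)
    while (v <= 0)
      v <- stats::rnorm(1L, p$wave_speed_mean_um_min, p$wave_speed_sd_um_min)
    speeds[i] <- v
  }

  # --- dynamics at sub-frame resolution (grid aligned with frame times) ---
  dt <- dt_frame / ceiling(dt_frame / 0.1)      # minutes
  n_steps <- ceiling(p$duration_min / dt)

  L <- p$initial_length_um
  area <- p$gc_area_um2
  peak <- NA_real_; t_peak <- NA_real_
  area_floor <- 0.35 * p$gc_area_um2
  w_s <- rep(NA_real_, n_w)                     # current arc position
  w_active <- rep(FALSE, n_w)
  w_pending <- rep(FALSE, n_w)                  # merged, not yet recorded
  w_done <- rep(FALSE, n_w)
  w_merge_t <- rep(NA_real_, n_w)
  w_retr_on <- rep(NA_real_, n_w)
  w_retr_um <- rep(0, n_w)
  w_completed <- rep(FALSE, n_w)

  L_fr <- numeric(n_frames); A_fr <- numeric(n_frames)
  s_fr <- matrix(NA_real_, n_frames, max(n_w, 1L))
  next_frame <- 1L
  t_now <- 0

  record_frame <- function(k) {
    L_fr[k] <<- L; A_fr[k] <<- area
    if (any(w_pending)) w_s[w_pending] <<- L   # a merged wave sits at the tip
    show <- w_active | w_pending
    if (n_w > 0 && any(show)) s_fr[k, which(show)] <<- pmin(w_s[show], L)
    w_pending[w_pending] <<- FALSE
  }
  # frame 0 state (waves with t0 == 0 activate below on the first step)
  record_frame(1L); next_frame <- 2L

  step_until <- if (n_frames > 1L) n_steps else 0L
  for (step in seq_len(step_until)) {
    t_next <- step * dt
    # incept
    newly <- which(!w_active & !w_done & t0 <= t_next)
    if (length(newly)) { w_active[newly] <- TRUE; w_s[newly] <- 0 }
    # advance waves
    act <- which(w_active)
    if (length(act)) w_s[act] <- w_s[act] + speeds[act] * dt
    # tip dynamics
    gaps <- L - w_s[act]
    approaching <- act[!is.na(gaps) & gaps > 0 & gaps <= p$approach_distance_um]
    if (length(approaching)) {
      lead <- approaching[which.min(L - w_s[approaching])]
      rate <- p$gc_retraction_um * speeds[lead] /
        (p$approach_distance_um - p$gc_retraction_um)
      dL <- -rate * dt
      if (is.na(w_retr_on[lead])) w_retr_on[lead] <- t_next
      w_retr_um[lead] <- w_retr_um[lead] + rate * dt
    } else if (length(act)) {
      dL <- p$growth_speed_waves_um_min * dt
    } else {
      dL <- p$growth_speed_free_um_min * dt
    }
    L <- min(max(L + dL, p$hillock_arc_um + 2), arc_max)
    # merges
    merged <- act[!is.na(w_s[act]) & w_s[act] >= L]
    for (i in merged) {
      w_s[i] <- L
      w_active[i] <- FALSE; w_done[i] <- TRUE; w_pending[i] <- TRUE
      w_merge_t[i] <- t_next; w_completed[i] <- TRUE
      peak <- min(p$gc_area_fold_on_merge * area, p$gc_area_max_um2)
      t_peak <- t_next
      area <- peak
    }
    # GC area decay after a merge
    if (!is.na(peak))
      area <- max(area_floor, peak * 2^(-(t_next - t_peak) / p$gc_area_halflife_min))
    # record any frame times passed
    while (next_frame <= n_frames && t_frames[next_frame] <= t_next + 1e-9) {
      record_frame(next_frame); next_frame <- next_frame + 1L
    }
  }
  while (next_frame <= n_frames) { record_frame(next_frame); next_frame <- next_frame + 1L }

  waves <- data.frame(
    id = seq_len(n_w), t0_min = t0, speed_um_min = speeds,
    completed = w_completed, merge_time_min = w_merge_t,
    retraction_onset_min = w_retr_on, retraction_um = w_retr_um
  )[seq_len(n_w), , drop = FALSE]

  soma_xy <- backbone_at(fine, 0)
  px <- p$pixel_size_um
  soma_px <- c(r = soma_xy[1, "r"] / px + 0.5, c = soma_xy[1, "c"] / px + 0.5)
  hill_xy <- backbone_at(fine, p$hillock_arc_um)
  tip_xy0 <- backbone_at(fine, L_fr[1])
  seeds <- list(
    soma_point = round(soma_px),
    hillock_point = round(c(hill_xy[1, 1] / px + 0.5, hill_xy[1, 2] / px + 0.5)),
    edge_point = round(c(tip_xy0[1, 1] / px + 0.5, tip_xy0[1, 2] / px + 0.5)),
    wave_point = NULL
  )

  truth <- structure(list(
    time_s = t_frames * 60,
    L_um = L_fr,
    gc_area_um2 = A_fr,
    wave_arc = s_fr[, seq_len(n_w), drop = FALSE],
    waves = waves,
    soma_centroid_px = soma_px,
    backbone = fine,
    seeds = seeds,
    pixel_size_um = px,
    frame_interval_s = p$frame_interval_s,
    image_shape = p$image_shape,
    params = p
  ), class = "aw_ground_truth")

  stack <- NULL
  if (render) {
    frames <- array(0, c(p$image_shape[1], p$image_shape[2], n_frames))
    for (k in seq_len(n_frames)) {
      scene <- render_scene(p, fine, L_fr[k], A_fr[k],
                            s_fr[k, seq_len(n_w)], speeds)
      noisy <- stats::rpois(length(scene), lambda = scene) +
        stats::rnorm(length(scene), 0, p$read_noise_sd)
      frames[, , k] <- pmin(pmax(matrix(noisy, nrow(scene)), 0), 4095)
    }
    stack <- calibrated_stack(frames, px, p$frame_interval_s, channel = "actin")
  }
  structure(list(stack = stack, truth = truth), class = "aw_simulation")
}

#' Render one noise-free scene frame
#'
#' Exposed so tests can compare rendered geometry (e.g. the intensity-weighted
#' wave centroid) against the ground truth without noise.
#'
#' @param p \code{sim_movie_params}.
#' @param fine resampled backbone (from the ground truth \code{$backbone}).
#' @param L_um neurite length; \code{area_um2} GC area; \code{wave_arcs}
#'   active wave arc positions (NA = inactive); \code{speeds} unused lengths
#'   tolerated.
#' @keywords internal
render_scene <- function(p, fine, L_um, area_um2, wave_arcs, speeds) {
  px <- p$pixel_size_um
  H <- p$image_shape[1]; W <- p$image_shape[2]
  scene <- matrix(p$background_level, H, W)

  stamp <- function(scene, r_px, c_px, sigma_px, weight) {
    # add weight * exp(-d^2 / 2 sigma^2) around a (possibly fractional) centre
    rad <- ceiling(3 * sigma_px)
    r0 <- max(1L, floor(r_px) - rad); r1 <- min(H, floor(r_px) + rad + 1L)
    c0 <- max(1L, floor(c_px) - rad); c1 <- min(W, floor(c_px) + rad + 1L)
    if (r0 > r1 || c0 > c1) return(scene)
    rr <- r0:r1; cc <- c0:c1
    g <- outer(exp(-(rr - r_px)^2 / (2 * sigma_px^2)),
               exp(-(cc - c_px)^2 / (2 * sigma_px^2)))
    scene[rr, cc] <- scene[rr, cc] + weight * g
    scene
  }

  # soma blob
  soma <- backbone_at(fine, 0)
  scene <- stamp(scene, soma[1, 1] / px + 0.5, soma[1, 2] / px + 0.5,
                 p$soma_sigma_um / px, 0.8 * p$amplitude)

  # neurite tube: line of Gaussian stamps with density-normalised weights
  step_px <- 0.6
  sig_n <- p$neurite_sigma_um / px
  arcs <- seq(0, L_um, by = step_px * px)
  pos <- backbone_at(fine, arcs)
  w_tube <- 0.25 * p$amplitude * step_px / (sqrt(2 * pi) * sig_n)
  for (i in seq_along(arcs))
    scene <- stamp(scene, pos[i, 1] / px + 0.5, pos[i, 2] / px + 0.5,
                   sig_n, w_tube)

  # waves: widened, brighter bumps travelling along the backbone
  for (s in wave_arcs[!is.na(wave_arcs)]) {
    a0 <- max(0, s - 3 * p$wave_sigma_um)
    a1 <- min(L_um, s + 3 * p$wave_sigma_um)
    if (a1 <= a0) next
    arcs_w <- seq(a0, a1, by = step_px * px)
    pos_w <- backbone_at(fine, arcs_w)
    g_long <- exp(-(arcs_w - s)^2 / (2 * p$wave_sigma_um^2))
    sig_lat <- sig_n * (1 + p$wave_flare * g_long)
    w_w <- p$amplitude * g_long * step_px / (sqrt(2 * pi) * sig_lat)
    for (i in seq_along(arcs_w))
      scene <- stamp(scene, pos_w[i, 1] / px + 0.5, pos_w[i, 2] / px + 0.5,
                     sig_lat[i], w_w[i])
  }

  # growth cone: sharp disc of exactly the state area at the tip
  tip <- backbone_at(fine, L_um)
  r_gc <- sqrt(area_um2 / pi) / px
  tr <- tip[1, 1] / px + 0.5; tc <- tip[1, 2] / px + 0.5
  rad <- ceiling(r_gc) + 1L
  rr <- max(1L, floor(tr) - rad):min(H, floor(tr) + rad + 1L)
  cc <- max(1L, floor(tc) - rad):min(W, floor(tc) + rad + 1L)
  d2 <- outer((rr - tr)^2, rep(1, length(cc))) +
    outer(rep(1, length(rr)), (cc - tc)^2)
  scene[rr, cc] <- scene[rr, cc] + 0.9 * p$amplitude * (d2 <= r_gc^2)
  scene
}

#' Build a trajectory directly from simulator ground truth
#'
#' Equivalent to a perfectly supervised tracking of the simulated movie:
#' per-frame neurite length, most-distal wave arc position, and complete
#' per-wave tracks, in the same container \code{\link{track_trajectory}}
#' returns.
#'
#' @param truth an \code{aw_ground_truth}.
#' @return an \code{aw_trajectory} data frame.
#' @export
truth_trajectory <- function(truth) {
  stopifnot(inherits(truth, "aw_ground_truth"))
  n <- length(truth$time_s)
  s_um <- rep(NA_real_, n)
  if (ncol(truth$wave_arc) > 0)
    s_um <- apply(truth$wave_arc, 1, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  tr <- data.frame(
    frame = seq_len(n),
    time_s = truth$time_s,
    L_um = truth$L_um,
    s_um = s_um,
    wave_present = !is.na(s_um)
  )
  tracks <- lapply(seq_len(ncol(truth$wave_arc)), function(j) {
    ok <- !is.na(truth$wave_arc[, j])
    data.frame(frame = which(ok), time_s = truth$time_s[ok],
               s_um = truth$wave_arc[ok, j], L_um = truth$L_um[ok])
  })
  tracks <- Filter(function(d) nrow(d) > 0, tracks)
  attr(tr, "wave_tracks") <- tracks
  attr(tr, "pixel_size_um") <- truth$pixel_size_um
  attr(tr, "merge_tolerance_um") <- truth$params$merge_tolerance_um
  class(tr) <- c("aw_trajectory", "data.frame")
  tr
}

#' Simulate a cohort of neurites with heterogeneous wave rates
#'
#' Emulates a population in which some neurites see almost no waves and
#' others many: per-neurite inception rates are drawn uniformly over
#' \code{rate_range}. Rendering is skipped; the returned trajectories are the
#' ground-truth ones.
#'
#' @param n_neurites cohort size.
#' @param rate_range waves/hour range for the per-neurite Poisson rate.
#' @param duration_min observation span per neurite (default 8 h).
#' @param seed integer seed for the whole cohort.
#' @param ... overrides passed to \code{\link{sim_movie_params}}.
#' @return list of \code{aw_simulation} objects (stacks NULL).
#' @export
simulate_cohort <- function(n_neurites = 50, rate_range = c(0.1, 3),
                            duration_min = 480, seed = 1L, ...) {
  set.seed(seed)
  rates <- stats::runif(n_neurites, rate_range[1], rate_range[2])
  seeds <- sample.int(2^31 - 2, n_neurites)
  lapply(seq_len(n_neurites), function(i) {
    p <- sim_movie_params("paper-regime-20x",
                          duration_min = duration_min,
                          wave_rate_per_h = rates[i],
                          image_shape = c(128L, 800L),
                          initial_length_um = 30,
                          rng_seed = seeds[i], ...)
    simulate_movie(p, render = FALSE)
  })
}
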