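# Synthetic two-channel STED-like scenes (actin + myosin puncta) with known
# per-ROI puncta densities, and synthetic two-channel line-scan traces.

#' Parameters for a synthetic STED scene
#'
#' Presets plant the reported density regimes: "sted-aw" uses an actin wave
#' with central rear 8.2 and central front 7.3 puncta/um^2, a peripheral
#' lamellipodium, and two equal-area (about 10 um^2) neurite sections before
#' and after the wave at 5.8 / 3.4 puncta/um^2; "sted-gc" uses a growth cone
#' with 10.5 (central/transition) versus 0.9 (peripheral) puncta/um^2.
#'
#' @param preset "sted-aw" or "sted-gc".
#' @param pixel_size_um pixel size (default 0.02 um = 20 nm).
#' @param densities named vector of puncta/um^2 overriding the preset.
#' @param actin_means named vector of per-ROI actin mean intensities.
#' @param punctum_sigma_um Gaussian sigma of a rendered punctum.
#' @param punctum_amplitude peak intensity of one punctum.
#' @param myosin_bg,actin_bg background levels per channel.
#' @param read_noise_sd Gaussian read noise sd.
#' @param exact_counts if TRUE, plant exactly round(density x area) puncta
#'   per ROI instead of a Poisson draw, so the planted rear/front contrast is
#'   definite rather than sampled.
#' @param rng_seed integer seed.
#' @return object of class \code{sim_sted_params}.
#' @export
sim_sted_params <- function(preset = c("sted-aw", "sted-gc"),
                            pixel_size_um = 0.02,
                            densities = NULL, actin_means = NULL,
                            punctum_sigma_um = 0.024,
                            punctum_amplitude = 1000,
                            myosin_bg = 10, actin_bg = 20,
                            read_noise_sd = 2, exact_counts = FALSE,
                            rng_seed = 1L) {
  preset <- match.arg(preset)
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(punctum_sigma_um, "punctum_sigma_um")
  check_positive(punctum_amplitude, "punctum_amplitude")
  rect <- function(x0, x1, r0, r1)  # (row_um, col_um) vertices
    cbind(r = c(r0, r0, r1, r1), c = c(x0, x1, x1, x0))
  if (preset == "sted-aw") {
    scene_um <- c(8, 20)
    rois_um <- list(
      neurite_proximal = rect(2.0, 5.2, 2.5, 5.5),     # 9.6 um^2
      AW_central_rear = rect(7.0, 10.0, 2.8, 5.2),
      AW_central_front = rect(10.0, 13.0, 2.8, 5.2),
      AW_peripheral = rect(7.0, 13.0, 0.8, 2.6),
      neurite_distal = rect(15.0, 18.2, 2.5, 5.5)      # 9.6 um^2
    )
    dens <- c(neurite_proximal = 5.8, AW_central_rear = 8.2,
              AW_central_front = 7.3, AW_peripheral = 2.0,
              neurite_distal = 3.4)
    amean <- c(neurite_proximal = 60, AW_central_rear = 100,
               AW_central_front = 120, AW_peripheral = 40,
               neurite_distal = 50)
  } else {
    scene_um <- c(12, 14)
    rois_um <- list(
      GC_central_transition = rect(2.0, 6.0, 4.0, 8.0),
      GC_peripheral = rect(7.5, 11.5, 3.0, 9.0)
    )
    dens <- c(GC_central_transition = 10.5, GC_peripheral = 0.9)
    amean <- c(GC_central_transition = 120, GC_peripheral = 30)
  }
  if (!is.null(densities)) dens[names(densities)] <- densities
  if (!is.null(actin_means)) amean[names(actin_means)] <- actin_means
  check_nonneg(unname(dens), "densities")
  p <- structure(list(preset = preset, pixel_size_um = pixel_size_um,
                      scene_um = scene_um, rois_um = rois_um,
                      densities = dens, actin_means = amean,
                      punctum_sigma_um = punctum_sigma_um,
                      punctum_amplitude = punctum_amplitude,
                      myosin_bg = myosin_bg, actin_bg = actin_bg,
                      read_noise_sd = read_noise_sd,
                      exact_counts = isTRUE(exact_counts),
                      rng_seed = rng_seed),
                 class = "sim_sted_params")
  p
}

#' Simulate a two-channel STED-like scene
#'
#' The myosin channel contains, per ROI, a Poisson-distributed number of
#' puncta (expectation density x area) at uniformly random in-ROI positions,
#' rendered as small Gaussian spots; the actin channel carries the declared
#' per-ROI mean intensities plus a filament texture. Both channels get
#' Poisson shot noise and Gaussian read noise. Identical seeds give
#' bit-identical output.
#'
#' @param params a \code{\link{sim_sted_params}}.
#' @param render if FALSE, skip rendering the channels (ground truth only).
#' @return list of class \code{sted_simulation} with \code{myosin},
#'   \code{actin} (matrices), \code{rois} (list of
#'   \code{\link{region_of_interest}} in pixel coordinates), \code{truth}
#'   (data.frame: punctum r, c in pixels and ROI label) and
#'   \code{truth_counts} (realised puncta per ROI).
#' @export
simulate_sted_scene <- function(params, render = TRUE) {
  stopifnot(inherits(params, "sim_sted_params"))
  p <- params
  px <- p$pixel_size_um
  H <- round(p$scene_um[1] / px); W <- round(p$scene_um[2] / px)
  set.seed(p$rng_seed)

  rois <- lapply(names(p$rois_um), function(lb) {
    poly_px <- p$rois_um[[lb]] / px + 0.5
    region_of_interest(poly_px, lb, px)
  })
  names(rois) <- names(p$rois_um)

  # overlapping ROIs with conflicting labels are a geometry error; polygons
  # are shrunk infinitesimally toward their centroid so ROIs that merely
  # share a boundary do not count as overlapping
  shrink <- function(poly) {
    mid <- colMeans(poly)
    sweep(poly, 2, mid, "-") * (1 - 1e-9) + rep(mid, each = nrow(poly))
  }
  for (i in seq_along(rois)) for (j in seq_len(i - 1L)) {
    a <- shrink(rois[[i]]$polygon); b <- shrink(rois[[j]]$polygon)
    mid <- colMeans(a)
    if (any(point_in_polygon(a[, 2], a[, 1], b[, c(2, 1)])) ||
        any(point_in_polygon(b[, 2], b[, 1], a[, c(2, 1)])) ||
        point_in_polygon(mid[2], mid[1], b[, c(2, 1)]))
      wt_stop(sprintf("ROIs '%s' and '%s' overlap", names(rois)[i],
                      names(rois)[j]), "geometry_error")
  }

  # plant puncta
  truth <- list()
  for (lb in names(rois)) {
    roi <- rois[[lb]]
    n <- if (isTRUE(p$exact_counts)) round(p$densities[[lb]] * roi$area_um2)
         else stats::rpois(1L, p$densities[[lb]] * roi$area_um2)
    if (n == 0) next
    bb_r <- range(roi$polygon[, 1]); bb_c <- range(roi$polygon[, 2])
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      cand_r <- stats::runif(n, bb_r[1], bb_r[2])
      cand_c <- stats::runif(n, bb_c[1], bb_c[2])
      ok <- point_in_polygon(cand_c, cand_r, roi$polygon[, c(2, 1)])
      pts <- rbind(pts, cbind(cand_r[ok], cand_c[ok]))
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    truth[[lb]] <- data.frame(r = pts[, 1], c = pts[, 2], label = lb)
  }
  truth <- do.call(rbind, truth) %||%
    data.frame(r = numeric(0), c = numeric(0), label = character(0))
  rownames(truth) <- NULL

  counts <- vapply(names(rois), function(lb) sum(truth$label == lb), 1L)
  if (!render)
    return(structure(list(myosin = NULL, actin = NULL, rois = rois,
                          truth = truth, truth_counts = counts, params = p),
                     class = "sted_simulation"))

  # render myosin channel
  myo <- matrix(p$myosin_bg, H, W)
  sig <- p$punctum_sigma_um / px
  rad <- ceiling(4 * sig)
  for (i in seq_len(nrow(truth))) {
    rr <- max(1L, floor(truth$r[i]) - rad):min(H, floor(truth$r[i]) + rad + 1L)
    cc <- max(1L, floor(truth$c[i]) - rad):min(W, floor(truth$c[i]) + rad + 1L)
    g <- outer(exp(-(rr - truth$r[i])^2 / (2 * sig^2)),
               exp(-(cc - truth$c[i])^2 / (2 * sig^2)))
    myo[rr, cc] <- myo[rr, cc] + p$punctum_amplitude * g
  }

  # render actin channel: per-ROI plateau + gentle filament texture
  act <- matrix(p$actin_bg, H, W)
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (lb in names(rois)) {
    inpoly <- point_in_polygon(as.vector(cols), as.vector(rows),
                               rois[[lb]]$polygon[, c(2, 1)])
    act[matrix(inpoly, H, W)] <- p$actin_means[[lb]]
  }
  n_fil <- 6L
  for (f in seq_len(n_fil)) {
    r0 <- stats::runif(1, H * 0.3, H * 0.7)
    amp <- stats::runif(1, 2, H * 0.1)
    ph <- stats::runif(1, 0, 2 * pi)
    rr <- r0 + amp * sin(seq_len(W) / W * 4 * pi + ph)
    sig_f <- 0.05 / px
    d <- abs(rows - matrix(rr, H, W, byrow = TRUE))
    act <- act + 8 * exp(-d^2 / (2 * sig_f^2))
  }

  noisy <- function(img) {
    v <- stats::rpois(length(img), lambda = img) +
      stats::rnorm(length(img), 0, p$read_noise_sd)
    pmin(pmax(matrix(v, nrow(img)), 0), 65535)
  }
  myo <- noisy(myo); act <- noisy(act)

  structure(list(myosin = myo, actin = act, rois = rois, truth = truth,
                 truth_counts = counts, params = p),
            class = "sted_simulation")
}

#' Simulate two-channel line-scan traces with a planted peak offset
#'
#' Each trace carries an actin wave profile (Gaussian bump on a baseline)
#' and a myosin profile whose peak sits \code{myosin_offset_um} behind the
#' actin peak (toward the soma; arc increases toward the growth cone).
#' Traces differ by random wave position, overall intensity scale and
#' additive noise.
#'
#' @param n_traces number of traces.
#' @param length_um trace length; \code{step_um} sampling step.
#' @param actin_sigma_um,myosin_sigma_um bump widths.
#' @param myosin_offset_um planted peak-to-peak offset (default 5).
#' @param peak_snr bump amplitude over noise sd.
#' @param seed integer seed.
#' @return list of \code{\link{linescan_trace}} objects with channels
#'   "actin" and "myosin"; the planted offset is attached as attribute
#'   \code{planted_offset_um}.
#' @export
simulate_linescan_traces <- function(n_traces = 16, length_um = 60,
                                     step_um = 0.2, actin_sigma_um = 4,
                                     myosin_sigma_um = 4,
                                     myosin_offset_um = 5, peak_snr = 20,
                                     seed = 1L) {
  set.seed(seed)
  arc <- seq(0, length_um, by = step_um)
  out <- lapply(seq_len(n_traces), function(i) {
    centre <- stats::runif(1, length_um * 0.35, length_um * 0.65)
    scale <- stats::runif(1, 0.5, 2)
    base <- 5
    amp <- 100
    noise_sd <- amp / peak_snr
    actin <- base + amp * exp(-(arc - centre)^2 / (2 * actin_sigma_um^2)) +
      stats::rnorm(length(arc), 0, noise_sd)
    myo <- base + 0.8 * amp *
      exp(-(arc - (centre - myosin_offset_um))^2 / (2 * myosin_sigma_um^2)) +
      stats::rnorm(length(arc), 0, noise_sd)
    linescan_trace(arc, list(actin = pmax(actin, 0) * scale,
                             myosin = pmax(myo, 0) * scale),
                   source_id = paste0("sim", i))
  })
  attr(out, "planted_offset_um") <- myosin_offset_um
  out
}
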