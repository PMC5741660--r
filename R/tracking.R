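# Soma extraction, geodesic neurite-length measurement, seeded per-frame
# tracking of hillock / edge / wave points, and kymograph construction.

# Pixel graph over the foreground of a binary mask: 8-connected, axial steps
# cost 1, diagonal steps cost sqrt(2) (pixel units).
mask_graph <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  pos <- integer(H * W); pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  shifts <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  for (s in shifts) {
    r2 <- r + s[[1]]; c2 <- co + s[[2]]
    ok <- r2 >= 1L & r2 <= H & c2 <= W & c2 >= 1L
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- mask[nb]
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[nb[hit]])
    wt <- c(wt, rep(s[[3]], sum(hit)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  list(graph = g, idx = idx, pos = pos, weights = wt)
}

as_mask <- function(map) {
  if (inherits(map, "feature_map")) map$binary
  else if (is.matrix(map)) map != 0
  else wt_stop("expected a feature_map or a matrix", "validation_error",
               field = "map")
}

px_index <- function(mask, p, name) {
  H <- nrow(mask); W <- ncol(mask)
  if (length(p) != 2L || any(p < 1) || p[1] > H || p[2] > W)
    wt_stop(sprintf("%s (%s) lies outside the image", name,
                    paste(p, collapse = ",")), "seed_error", point = p)
  (round(p[2]) - 1L) * H + round(p[1])
}

#' Geodesic length between two points on a binary map
#'
#' Exact shortest 8-connected path cost restricted to above-threshold pixels,
#' with axial steps weighted 1 and diagonal steps sqrt(2), converted to
#' micrometres.
#'
#' @param map a \code{feature_map} or binary matrix.
#' @param p1,p2 pixel coordinates c(row, col), 1-based, on the foreground.
#' @param pixel_size_um micrometres per pixel.
#' @return length in micrometres.
#' @export
geodesic_length <- function(map, p1, p2, pixel_size_um) {
  check_positive(pixel_size_um, "pixel_size_um")
  mask <- as_mask(map)
  i1 <- px_index(mask, p1, "p1"); i2 <- px_index(mask, p2, "p2")
  if (!mask[i1])
    wt_stop(sprintf("p1 (%d,%d) is on background", round(p1[1]), round(p1[2])),
            "seed_error", point = p1)
  if (!mask[i2])
    wt_stop(sprintf("p2 (%d,%d) is on background", round(p2[1]), round(p2[2])),
            "seed_error", point = p2)
  mg <- mask_graph(mask)
  d <- igraph::distances(mg$graph, v = mg$pos[i1], to = mg$pos[i2],
                         weights = mg$weights, algorithm = "dijkstra")[1, 1]
  if (!is.finite(d))
    wt_stop("p1 and p2 lie in different components", "disconnection_error")
  d * pixel_size_um
}

# Geodesic distances (pixel units) from a source pixel to every foreground
# pixel; Inf outside the source's component.
geodesic_field <- function(mask, source_idx, mg = NULL) {
  if (is.null(mg)) mg <- mask_graph(mask)
  d <- rep(Inf, nrow(mask) * ncol(mask))
  dv <- igraph::distances(mg$graph, v = mg$pos[source_idx],
                          weights = mg$weights, algorithm = "dijkstra")[1, ]
  d[mg$idx] <- dv
  d
}

#' Extract the cell body by seeded region growing
#'
#' Grows the connected above-threshold region from the seed, clipped to a
#' maximum radius, and returns the mask and intensity-weighted centroid. The
#' centroid is the origin of the arc-length coordinate system.
#'
#' @param image intensity matrix (or \code{feature_map}, whose binary map is
#'   then used with unit weights).
#' @param soma_seed c(row, col) seed inside the soma.
#' @param threshold intensity cutoff; NULL uses Otsu's threshold on the image.
#' @param max_radius_px clip the region to this radius around the seed.
#' @return list with \code{mask} (logical matrix) and \code{centroid}
#'   (c(row, col), fractional pixels).
#' @export
extract_soma <- function(image, soma_seed, threshold = NULL, max_radius_px = 40) {
  if (inherits(image, "feature_map")) {
    mask0 <- image$binary
    weights <- matrix(1, nrow(mask0), ncol(mask0))
  } else {
    if (is.null(threshold)) {
      rng <- range(image)
      threshold <- if (diff(rng) <= 0) rng[2] + 1 else
        EBImage::otsu(EBImage::Image((image - rng[1]) / diff(rng))) * diff(rng) + rng[1]
    }
    mask0 <- image >= threshold
    weights <- image
  }
  i0 <- px_index(mask0, soma_seed, "soma_seed")
  if (!mask0[i0])
    wt_stop(sprintf("soma seed (%d,%d) is on background",
                    round(soma_seed[1]), round(soma_seed[2])),
            "seed_error", point = soma_seed)
  H <- nrow(mask0); W <- ncol(mask0)
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  near <- (rr - soma_seed[1])^2 + (cc - soma_seed[2])^2 <= max_radius_px^2
  mask <- mask0 & near
  lab <- label_components(mask, 8)
  mask <- lab == lab[i0]
  w <- weights[mask]
  centroid <- c(sum(rr[mask] * w), sum(cc[mask] * w)) / sum(w)
  list(mask = mask, centroid = centroid)
}

# Nearest foreground pixel (linear index) to a (row, col) point, optionally
# within a radius; NA if none.
nearest_fg <- function(mask, p, radius = Inf) {
  idx <- which(mask)
  if (!length(idx)) return(NA_integer_)
  H <- nrow(mask)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  d2 <- (r - p[1])^2 + (co - p[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > radius) NA_integer_ else idx[i]
}

#' Track soma, hillock, edge and wave positions through a movie
#'
#' For each frame the tracked points are re-localised to the best-matching
#' feature-map pixel within \code{search_radius_px} of their previous
#' position (the edge is the geodesically farthest component pixel within the
#' search region). Neurite length L(t) and wave arc position s(t) are geodesic
#' distances from the projection of the soma centroid onto the component.
#' Wave candidates are bright blobs along the component (intensity above the
#' shaft level by \code{wave_factor}); frames with no candidate carry the
#' no-wave flag, and all concurrent candidates are linked across frames into
#' per-wave tracks (attribute \code{wave_tracks}).
#'
#' @param stack a \code{\link{calibrated_stack}}.
#' @param maps list of \code{\link{make_feature_map}} results, one per frame.
#' @param seeds list with \code{soma_point}, \code{hillock_point},
#'   \code{edge_point} and optionally \code{wave_point}, each c(row, col) on
#'   frame 1 (as produced by the simulator or read from a seed file).
#' @param search_radius_px search radius for re-localisation.
#' @param wave_factor a blob counts as a wave when its denoised intensity
#'   exceeds background + wave_factor * (shaft level - background).
#' @param denoise_sigma_px Gaussian sigma applied before intensity readout.
#' @param soma_exclude_um,gc_exclude_um arc bands near the soma and the tip
#'   excluded from wave candidacy (the soma and growth cone are themselves
#'   bright).
#' @param corrections optional data.frame(frame, point, r, c) of manual
#'   overrides ("soma", "hillock", "edge", "wave"), the supervision hook.
#' @param max_gap_frames a wave track is closed after this many frames
#'   without a matched candidate.
#' @return an \code{aw_trajectory} data frame (one row per frame) with
#'   attributes \code{wave_tracks}, \code{pixel_size_um}.
#' @export
track_trajectory <- function(stack, maps, seeds, search_radius_px = 25,
                             wave_factor = 1.5, denoise_sigma_px = 1,
                             soma_exclude_um = 12, gc_exclude_um = 12,
                             corrections = NULL, max_gap_frames = 2) {
  stopifnot(inherits(stack, "calibrated_stack"))
  n <- dim(stack$frames)[3]
  if (length(maps) != n)
    wt_stop("need one feature map per frame", "validation_error", field = "maps")
  px <- stack$pixel_size_um
  times <- frame_times(stack)

  mask1 <- as_mask(maps[[1]])
  for (nm in c("soma_point", "hillock_point", "edge_point"))
    px_index(mask1, seeds[[nm]], nm)

  soma_prev <- as.numeric(seeds$soma_point)
  hill_prev <- as.numeric(seeds$hillock_point)
  edge_prev <- as.numeric(seeds$edge_point)

  out <- data.frame(frame = seq_len(n), time_s = times,
                    L_um = NA_real_, s_um = NA_real_, wave_present = FALSE,
                    gap = FALSE,
                    soma_r = NA_real_, soma_c = NA_real_,
                    hillock_r = NA_real_, hillock_c = NA_real_,
                    edge_r = NA_real_, edge_c = NA_real_)
  tracks <- list()          # closed + open wave tracks
  open_id <- integer(0)     # indices into `tracks` still active
  open_last_frame <- integer(0)
  edge_gaps <- 0L           # consecutive frames with a lost edge

  get_corr <- function(f, what) {
    if (is.null(corrections)) return(NULL)
    hit <- corrections[corrections$frame == f & corrections$point == what, ]
    if (nrow(hit)) as.numeric(c(hit$r[1], hit$c[1])) else NULL
  }

  for (f in seq_len(n)) {
    frame <- stack$frames[, , f]
    mask <- as_mask(maps[[f]])
    I <- gaussian_denoise(frame, denoise_sigma_px)
    bg <- stats::median(I)

    # soma
    corr <- get_corr(f, "soma")
    soma_seed <- corr %||% soma_prev
    soma <- tryCatch(extract_soma(I, round(soma_seed)),
                     wavetrack_seed_error = function(e) NULL)
    soma_ctr <- if (is.null(soma)) soma_prev else soma$centroid
    out$soma_r[f] <- soma_ctr[1]; out$soma_c[f] <- soma_ctr[2]

    # arc-length origin: component pixel nearest the soma centroid
    origin <- nearest_fg(mask, soma_ctr, radius = search_radius_px * 2)
    if (is.na(origin)) { out$gap[f] <- TRUE; soma_prev <- soma_ctr; next }
    mg <- mask_graph(mask)
    D <- geodesic_field(mask, origin, mg)

    H <- nrow(mask)
    # hillock: nearest component pixel to its previous position
    corr <- get_corr(f, "hillock")
    hill_idx <- if (!is.null(corr)) nearest_fg(mask, corr, search_radius_px)
                else nearest_fg(mask, hill_prev, search_radius_px)
    if (!is.na(hill_idx))
      hill_prev <- c((hill_idx - 1L) %% H + 1L, (hill_idx - 1L) %/% H + 1L)
    out$hillock_r[f] <- hill_prev[1]; out$hillock_c[f] <- hill_prev[2]

    # edge: farthest (geodesic) component pixel within the search region;
    # after lost frames the region grows so the edge can be re-acquired
    corr <- get_corr(f, "edge")
    radius_f <- search_radius_px * min(1 + edge_gaps / 2, 3)
    if (!is.null(corr)) {
      edge_idx <- nearest_fg(mask, corr, radius_f)
    } else {
      idx <- which(mask)
      r <- ((idx - 1L) %% H) + 1L; co <- ((idx - 1L) %/% H) + 1L
      inreg <- (r - edge_prev[1])^2 + (co - edge_prev[2])^2 <= radius_f^2
      cand <- idx[inreg & is.finite(D[idx])]
      edge_idx <- if (length(cand)) cand[which.max(D[cand])] else NA_integer_
    }
    if (is.na(edge_idx)) {
      out$gap[f] <- TRUE
      edge_gaps <- edge_gaps + 1L
    } else {
      edge_gaps <- 0L
      edge_prev <- c((edge_idx - 1L) %% H + 1L, (edge_idx - 1L) %/% H + 1L)
      out$L_um[f] <- D[edge_idx] * px
    }
    out$edge_r[f] <- edge_prev[1]; out$edge_c[f] <- edge_prev[2]
    if (is.na(edge_idx)) { soma_prev <- soma_ctr; next }

    # wave candidates: bright blobs along the component, away from soma & GC
    shaft <- stats::median(I[mask])
    thr <- bg + wave_factor * max(shaft - bg, 0)
    cand_mask <- mask & (I > thr)
    arcs <- numeric(0)
    if (any(cand_mask)) {
      lab <- label_components(cand_mask, 8)
      er <- edge_prev[1]; ec <- edge_prev[2]
      for (b in seq_len(max(lab))) {
        bidx <- which(lab == b)
        br <- ((bidx - 1L) %% H) + 1L; bc <- ((bidx - 1L) %/% H) + 1L
        # the growth cone: any blob reaching the tracked edge point
        if (min((br - er)^2 + (bc - ec)^2) <= 9) next
        peak <- bidx[which.max(I[bidx])]
        a <- D[peak] * px
        if (!is.finite(a)) next
        if (a < soma_exclude_um) next
        # a blob extending into the soma-exclusion zone has its intensity
        # peak contaminated by the soma flank: localisation is unreliable
        if (suppressWarnings(min(D[bidx], na.rm = TRUE)) * px <
            soma_exclude_um) next
        if (!is.na(out$L_um[f]) && a > out$L_um[f] - gc_exclude_um) next
        # sub-pixel refinement: intensity-weighted arc centroid over the
        # bump core (+/- 3 um around the peak)
        barc <- D[bidx] * px
        sel <- is.finite(barc) & abs(barc - a) <= 3
        w <- pmax(I[bidx[sel]] - bg, 0)
        if (sum(w) > 0) a <- sum(w * barc[sel]) / sum(w)
        arcs <- c(arcs, a)
      }
    }
    corr <- get_corr(f, "wave")
    if (!is.null(corr)) {
      widx <- nearest_fg(mask, corr, search_radius_px)
      if (!is.na(widx)) arcs <- sort(unique(c(arcs, D[widx] * px)))
    }
    arcs <- sort(arcs)
    if (length(arcs)) {
      out$s_um[f] <- arcs[length(arcs)]   # most distal candidate
      out$wave_present[f] <- TRUE
    }

    # link candidates to open wave tracks (most distal first), matching each
    # track's velocity-predicted position
    dt_min <- stack$frame_interval_s / 60
    unmatched <- arcs
    order_k <- rev(order(vapply(open_id, function(ti)
      tracks[[ti]]$s_um[nrow(tracks[[ti]])], 1)))
    drop_k <- integer(0)
    for (k in order_k) {
      ti <- open_id[k]
      last <- tracks[[ti]]
      nlast <- nrow(last)
      la <- last$s_um[nlast]
      v_est <- if (nlast >= 2)
        (la - last$s_um[nlast - 1L]) /
          ((last$time_s[nlast] - last$time_s[nlast - 1L]) / 60)
      else 2.2                                    # anterograde prior, um/min
      v_est <- min(max(v_est, 0.5), 6)
      gap_f <- f - open_last_frame[k]
      if (gap_f > max_gap_frames + 1L) {  # unmatched for > max_gap_frames
        drop_k <- c(drop_k, k)
        next
      }
      pred <- la + v_est * dt_min * gap_f
      win <- max(4, 2 * px) + 2 * dt_min * gap_f  # prediction window, um
      # waves move anterogradely: require at least the same minimum speed
      # used in the velocity clamp, minus localisation jitter
      ok <- which(unmatched >= la + 0.5 * dt_min * gap_f - 2 &
                    abs(unmatched - pred) <= win)
      if (length(ok)) {
        j <- ok[which.min(abs(unmatched[ok] - pred))]
        tracks[[ti]] <- rbind(last, data.frame(frame = f, time_s = times[f],
                                               s_um = unmatched[j],
                                               L_um = out$L_um[f]))
        open_last_frame[k] <- f
        unmatched <- unmatched[-j]
      }
    }
    if (length(drop_k)) {
      open_id <- open_id[-drop_k]; open_last_frame <- open_last_frame[-drop_k]
    }
    for (a in unmatched) {
      tracks[[length(tracks) + 1L]] <- data.frame(frame = f, time_s = times[f],
                                                  s_um = a, L_um = out$L_um[f])
      open_id <- c(open_id, length(tracks))
      open_last_frame <- c(open_last_frame, f)
    }
    soma_prev <- soma_ctr
  }

  attr(out, "wave_tracks") <- tracks
  attr(out, "pixel_size_um") <- px
  attr(out, "search_radius_px") <- search_radius_px
  attr(out, "gc_exclude_um") <- gc_exclude_um
  class(out) <- c("aw_trajectory", "data.frame")
  out
}

#' Kymograph along a backbone path
#'
#' Row t holds the intensity profile along the path at frame t; each arc
#' sample is the maximum over a perpendicular segment of +/- half_width_px.
#'
#' @param stack a \code{\link{calibrated_stack}}.
#' @param path_px two-column matrix of (row, col) pixel coordinates tracing
#'   the path (e.g. the simulator backbone mapped to pixels).
#' @param half_width_px half-width of the perpendicular maximum-projection
#'   segment.
#' @return matrix with T rows and one column per arc sample at pixel pitch,
#'   with attribute \code{arc_px}.
#' @export
build_kymograph <- function(stack, path_px, half_width_px = 2) {
  stopifnot(inherits(stack, "calibrated_stack"))
  H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
  d <- sqrt(diff(path_px[, 1])^2 + diff(path_px[, 2])^2)
  arc <- c(0, cumsum(d))
  n_samp <- ceiling(arc[length(arc)])
  s <- seq(0, arc[length(arc)], length.out = max(n_samp, 2L))
  r <- stats::approx(arc, path_px[, 1], xout = s)$y
  c_ <- stats::approx(arc, path_px[, 2], xout = s)$y
  # tangents -> unit normals
  tr <- c(diff(r), r[length(r)] - r[length(r) - 1])
  tc <- c(diff(c_), c_[length(c_)] - c_[length(c_) - 1])
  nrm <- sqrt(tr^2 + tc^2); nrm[nrm == 0] <- 1
  nr <- -tc / nrm; nc <- tr / nrm
  offs <- seq(-half_width_px, half_width_px, by = 1)
  rs <- outer(r, rep(1, length(offs))) + outer(nr, offs)
  cs <- outer(c_, rep(1, length(offs))) + outer(nc, offs)
  if (any(rs < 1 | rs > H | cs < 1 | cs > W))
    wt_stop("path (plus half width) escapes the frame", "geometry_error")
  TT <- dim(stack$frames)[3]
  ky <- matrix(0, TT, length(s))
  for (t in seq_len(TT)) {
    vals <- bilinear_sample(stack$frames[, , t], as.vector(rs), as.vector(cs))
    ky[t, ] <- apply(matrix(vals, nrow(rs)), 1, max)
  }
  attr(ky, "arc_px") <- s
  ky
}
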