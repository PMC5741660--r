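# Geodesic lengths, soma extraction, point tracking, kymographs.

test_that("geodesic length handles collinear and diagonal paths exactly", {
  m <- matrix(FALSE, 20, 20)
  m[10, 5:14] <- TRUE
  expect_equal(geodesic_length(m, c(10, 5), c(10, 14), 0.5), 9 * 0.5)
  d <- matrix(FALSE, 20, 20)
  for (i in 0:8) d[5 + i, 5 + i] <- TRUE
  expect_equal(geodesic_length(d, c(5, 5), c(13, 13), 1), 8 * sqrt(2))
})

test_that("geodesic length signals seed and disconnection errors", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2:4] <- TRUE; m[8, 6:8] <- TRUE
  expect_error(geodesic_length(m, c(5, 5), c(2, 2), 1),
               class = "wavetrack_seed_error")
  expect_error(geodesic_length(m, c(2, 2), c(8, 7), 1),
               class = "wavetrack_disconnection_error")
})

test_that("geodesic length equals an independent Dijkstra on random masks", {
  set.seed(17)
  for (i in 1:25) {
    rm <- random_connected_mask(40, 40, 120)
    pts <- rm$pts[!duplicated(rm$pts), , drop = FALSE]
    p1 <- pts[1, ]; p2 <- pts[nrow(pts), ]
    got <- geodesic_length(rm$mask, p1, p2, 1)
    expect_equal(got, oracle_dijkstra(rm$mask, p1, p2), tolerance = 1e-12)
  }
})

test_that("geodesic length is symmetric and satisfies the triangle inequality", {
  set.seed(18)
  for (i in 1:10) {
    rm <- random_connected_mask(32, 32, 100)
    pts <- rm$pts[!duplicated(rm$pts), , drop = FALSE]
    idx <- sample(nrow(pts), 3)
    a <- pts[idx[1], ]; b <- pts[idx[2], ]; c <- pts[idx[3], ]
    dab <- geodesic_length(rm$mask, a, b, 1)
    expect_equal(dab, geodesic_length(rm$mask, b, a, 1), tolerance = 1e-12)
    dac <- geodesic_length(rm$mask, a, c, 1)
    dcb <- geodesic_length(rm$mask, c, b, 1)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("soma extraction recovers a rendered disc", {
  img <- matrix(10, 80, 80)
  rr <- row(img); cc <- col(img)
  img[(rr - 40)^2 + (cc - 40)^2 <= 15^2] <- 500
  soma <- extract_soma(img, c(40, 40))
  expect_equal(sum(soma$mask), pi * 15^2, tolerance = 0.02)
  expect_lt(sqrt(sum((soma$centroid - c(40, 40))^2)), 0.5)
  expect_error(extract_soma(img, c(5, 5)), class = "wavetrack_seed_error")
})

make_static_stack <- function(n_frames = 10, L = 60) {
  p <- sim_movie_params(rng_seed = 1)
  fine <- wavetrack:::backbone_resample(p$neurite_backbone)
  scene <- wavetrack:::render_scene(p, fine, L, p$gc_area_um2, NA, numeric(0))
  frames <- array(rep(scene, n_frames), c(dim(scene), n_frames))
  list(stack = calibrated_stack(frames, p$pixel_size_um, p$frame_interval_s),
       p = p, fine = fine)
}

test_that("a stationary noise-free neurite tracks to constant positions", {
  st <- make_static_stack()
  maps <- lapply(1:10, function(f) make_feature_map(st$stack$frames[, , f]))
  soma_px <- wavetrack:::backbone_at(st$fine, 0) / st$p$pixel_size_um + 0.5
  hill_px <- wavetrack:::backbone_at(st$fine, 8) / st$p$pixel_size_um + 0.5
  tip_px <- wavetrack:::backbone_at(st$fine, 60) / st$p$pixel_size_um + 0.5
  seeds <- list(soma_point = round(soma_px), hillock_point = round(hill_px),
                edge_point = round(tip_px))
  tr <- track_trajectory(st$stack, maps, seeds)
  expect_true(all(abs(tr$L_um - tr$L_um[1]) <= st$p$pixel_size_um))
  expect_true(all(abs(tr$edge_r - tr$edge_r[1]) <= 1))
  expect_true(all(abs(tr$edge_c - tr$edge_c[1]) <= 1))
  # no wave was rendered: every frame carries the no-wave flag
  expect_true(all(!tr$wave_present))
})

test_that("a single simulated wave is recovered to ~2 px RMS", {
  p <- sim_movie_params(duration_min = 40, wave_times_min = 2, rng_seed = 8)
  sim <- simulate_movie(p)
  gt <- sim$truth
  res <- run_pipeline(sim$stack, gt$seeds,
                      pipeline_config(overrides = list(verbosity = 0)))
  tr <- res$trajectory
  both <- which(tr$wave_present & !is.na(gt$wave_arc[, 1]))
  expect_gte(length(both), 4)
  rms <- sqrt(mean((tr$s_um[both] - gt$wave_arc[both, 1])^2))
  expect_lt(rms, 2 * gt$pixel_size_um)
})

test_that("manual corrections override the automatic localisation", {
  st <- make_static_stack(n_frames = 3)
  maps <- lapply(1:3, function(f) make_feature_map(st$stack$frames[, , f]))
  soma_px <- round(wavetrack:::backbone_at(st$fine, 0) / st$p$pixel_size_um + 0.5)
  hill_px <- round(wavetrack:::backbone_at(st$fine, 8) / st$p$pixel_size_um + 0.5)
  tip_px <- round(wavetrack:::backbone_at(st$fine, 60) / st$p$pixel_size_um + 0.5)
  back_px <- round(wavetrack:::backbone_at(st$fine, 50) / st$p$pixel_size_um + 0.5)
  seeds <- list(soma_point = soma_px, hillock_point = hill_px,
                edge_point = tip_px)
  corr <- data.frame(frame = 2, point = "edge", r = back_px[1], c = back_px[2])
  tr <- track_trajectory(st$stack, maps, seeds, corrections = corr)
  expect_lt(tr$L_um[2], tr$L_um[1] - 5)   # pinned ~10 um short of the tip
})

test_that("kymograph rows are static for a static scene and slopes recover speed", {
  st <- make_static_stack(n_frames = 5)
  path <- cbind(st$fine$r, st$fine$c)[st$fine$arc <= 60, ] / st$p$pixel_size_um + 0.5
  ky <- build_kymograph(st$stack, path, half_width_px = 2)
  expect_equal(dim(ky), c(5L, length(attr(ky, "arc_px"))))
  for (t in 2:5) expect_equal(ky[t, ], ky[1, ])
  # moving bump
  p <- sim_movie_params(duration_min = 30, wave_times_min = 1, rng_seed = 5)
  sim <- simulate_movie(p)
  gt <- sim$truth
  fine <- gt$backbone
  path2 <- cbind(fine$r, fine$c)[fine$arc <= min(gt$L_um), ] /
    gt$pixel_size_um + 0.5
  ky2 <- build_kymograph(sim$stack, path2, half_width_px = 3)
  # per-frame argmax along the path tracks the wave; fit arc vs time
  act <- which(!is.na(gt$wave_arc[, 1]))
  act <- act[gt$wave_arc[act, 1] < min(gt$L_um) - 8 & gt$wave_arc[act, 1] > 10]
  # search the peak away from the bright soma and growth cone
  arcs_px <- attr(ky2, "arc_px") * gt$pixel_size_um
  win <- which(arcs_px > 12 & arcs_px < min(gt$L_um) - 10)
  peak_arc <- apply(ky2[act, win, drop = FALSE], 1, which.max)
  peak_arc <- arcs_px[win[peak_arc]]
  fit <- lm(peak_arc ~ I(gt$time_s[act] / 60))
  expect_equal(unname(coef(fit)[2]), gt$waves$speed_um_min[1],
               tolerance = 0.1)
  expect_error(build_kymograph(st$stack, cbind(c(1, 500), c(1, 5)), 2),
               class = "wavetrack_geometry_error")
})
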