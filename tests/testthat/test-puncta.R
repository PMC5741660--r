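# Puncta detection, ROI densities, actin normalisation, tendency classes.

render_spots <- function(centres, H = 200, W = 200, sigma = 1.2, amp = 1000,
                         bg = 10) {
  img <- matrix(bg, H, W)
  for (i in seq_len(nrow(centres))) {
    rr <- max(1, floor(centres[i, 1]) - 6):min(H, floor(centres[i, 1]) + 7)
    cc <- max(1, floor(centres[i, 2]) - 6):min(W, floor(centres[i, 2]) + 7)
    img[rr, cc] <- img[rr, cc] +
      amp * outer(exp(-(rr - centres[i, 1])^2 / (2 * sigma^2)),
                  exp(-(cc - centres[i, 2])^2 / (2 * sigma^2)))
  }
  img
}

test_that("a blank image yields zero puncta", {
  expect_equal(nrow(detect_puncta(matrix(10, 64, 64), 0.02)), 0)
})

test_that("well-separated spots are each recovered within 1 px", {
  set.seed(4)
  grid <- expand.grid(r = seq(15, 183, by = 24), c = seq(15, 183, by = 24))
  centres <- as.matrix(grid[sample(nrow(grid), 50), ]) +
    matrix(runif(100, -3, 3), 50, 2)
  img <- render_spots(centres)
  det <- detect_puncta(img, 0.02)
  expect_equal(nrow(det), 50)
  for (i in seq_len(50)) {
    d <- sqrt((det$r - centres[i, 1])^2 + (det$c - centres[i, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("two spots below the resolvable separation merge into one detection", {
  img <- render_spots(rbind(c(100, 100), c(100, 102.5)))
  det <- detect_puncta(img, 0.02)
  expect_equal(nrow(det), 1)
  img2 <- render_spots(rbind(c(100, 100), c(100, 112)))
  expect_equal(nrow(detect_puncta(img2, 0.02)), 2)
})

test_that("ROI density is count over area and normalisation is identity at the scene maximum", {
  px <- 0.02
  side_px <- sqrt(10) / px   # 10 um^2 square
  poly <- cbind(r = c(10, 10, 10 + side_px, 10 + side_px),
                c = c(10, 10 + side_px, 10 + side_px, 10))
  roi <- region_of_interest(poly, "AW_central_rear", px)
  expect_equal(roi$area_um2, 10, tolerance = 1e-6)
  set.seed(9)
  cent <- data.frame(r = runif(50, 11, 9 + side_px),
                     c = runif(50, 11, 9 + side_px))
  rec <- roi_density(cent, roi)
  expect_equal(rec$density_per_um2, 5)
  # actin normalisation: at the scene max the density is unchanged
  actin <- matrix(50, 200, 200)
  rec2 <- roi_density(cent, roi, actin, normalize = TRUE,
                      scene_max_actin_mean = 50)
  expect_equal(rec2$normalized_density, rec2$density_per_um2)
  # away from the max the density is scaled up by the relative actin deficit
  rec3 <- roi_density(cent, roi, actin, normalize = TRUE,
                      scene_max_actin_mean = 100)
  expect_equal(rec3$normalized_density, 2 * rec3$density_per_um2)
  expect_error(roi_density(cent, roi, actin * 0, normalize = TRUE),
               class = "wavetrack_normalization_error")
})

test_that("counts are additive over a partition of an ROI", {
  px <- 0.02
  set.seed(5)
  cent <- data.frame(r = runif(200, 20, 180), c = runif(200, 20, 180))
  whole <- region_of_interest(cbind(c(20, 20, 180, 180), c(20, 180, 180, 20)),
                              "AW_peripheral", px)
  left <- region_of_interest(cbind(c(20, 20, 180, 180), c(20, 100, 100, 20)),
                             "AW_peripheral", px)
  right <- region_of_interest(cbind(c(20, 20, 180, 180), c(100, 180, 180, 100)),
                              "AW_peripheral", px)
  n_whole <- roi_density(cent, whole)$count
  expect_equal(roi_density(cent, left)$count + roi_density(cent, right)$count,
               n_whole)
})

test_that("even-odd point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(8)
  poly <- cbind(x = c(1, 8, 9, 5, 2), y = c(1, 2, 7, 9, 6))
  px <- runif(500, 0, 10); py <- runif(500, 0, 10)
  mine <- wavetrack:::point_in_polygon(px, py, poly)
  ref <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))
  expect_equal(mine, as.logical(ref))
})

test_that("tendency classification applies the 12 percent stability band", {
  expect_equal(classify_tendency(10, 10), "stable")
  expect_equal(classify_tendency(10, 8.5), "decrease")   # -15 percent
  expect_equal(classify_tendency(10, 9.0), "stable")     # -10 percent
  expect_equal(classify_tendency(10, 11.5), "increase")  # +15 percent
  out <- classify_tendency(0, 5)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "undefined-change")
})

test_that("STED scene: zero density plants zero puncta; seeds reproduce bit-identically", {
  p0 <- sim_sted_params("sted-gc",
                        densities = c(GC_central_transition = 0,
                                      GC_peripheral = 0))
  sc0 <- simulate_sted_scene(p0)
  expect_equal(nrow(sc0$truth), 0)
  expect_equal(nrow(detect_puncta(sc0$myosin, p0$pixel_size_um)), 0)
  p <- sim_sted_params("sted-gc", rng_seed = 33)
  s1 <- simulate_sted_scene(p); s2 <- simulate_sted_scene(p)
  expect_identical(s1$myosin, s2$myosin)
  expect_identical(s1$actin, s2$actin)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted Poisson counts have the right expectation (sampler check)", {
  px <- 0.025
  counts <- vapply(1:50, function(sd) {
    p <- sim_sted_params("sted-gc", pixel_size_um = px, rng_seed = sd,
                         densities = c(GC_central_transition = 5,
                                       GC_peripheral = 0))
    sum(simulate_sted_scene(p)$truth$label == "GC_central_transition")
  }, 1L)
  area <- 16   # the GC central ROI is 4 x 4 um
  expect_lt(abs(mean(counts) - 5 * area), 3 * sqrt(5 * area / 50))
})

test_that("exact_counts plants exactly round(density x area) puncta", {
  p <- sim_sted_params("sted-gc", densities = c(GC_central_transition = 5,
                                                GC_peripheral = 1.25),
                       exact_counts = TRUE, rng_seed = 11)
  sc <- simulate_sted_scene(p, render = FALSE)
  expect_equal(unname(sc$truth_counts[["GC_central_transition"]]), 80L)
  expect_equal(unname(sc$truth_counts[["GC_peripheral"]]),
               round(1.25 * sc$rois$GC_peripheral$area_um2))
})

test_that("STED preset densities are recovered within 15 percent", {
  # AW preset plants the reported central rear/front regime (8.2 / 7.3)
  rel_err <- c()
  for (sd in 1:5) {
    p <- sim_sted_params("sted-aw", rng_seed = sd)
    sc <- simulate_sted_scene(p)
    det <- detect_puncta(sc$myosin, p$pixel_size_um)
    tab <- roi_density_table(det, sc$rois)
    for (lb in c("AW_central_rear", "AW_central_front")) {
      truth_d <- sc$truth_counts[[lb]] / sc$rois[[lb]]$area_um2
      got <- tab$density_per_um2[tab$label == lb]
      rel_err <- c(rel_err, abs(got - truth_d) / max(truth_d, 1e-9))
    }
  }
  expect_lt(mean(rel_err), 0.15)
})

test_that("overlapping ROIs with conflicting labels are a geometry error", {
  p <- sim_sted_params("sted-aw")
  p$rois_um$AW_central_front <- p$rois_um$AW_central_rear  # force overlap
  expect_error(simulate_sted_scene(p), class = "wavetrack_geometry_error")
})
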