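# Denoising and phase-congruency feature detection.

test_that("a flat field passes through the Gaussian filter unchanged", {
  out <- gaussian_denoise(matrix(10, 30, 30), 2)
  expect_equal(out, matrix(10, 30, 30), tolerance = 1e-12)
})

test_that("a unit impulse keeps unit mass with its maximum in place", {
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  out <- gaussian_denoise(img, 1)
  expect_equal(sum(out), 1, tolerance = 1e-6)
  expect_equal(which.max(out), 11L + 10L * 21L)
})

test_that("separable filtering equals direct dense convolution with reflection", {
  set.seed(21)
  img <- matrix(runif(48 * 48, 0, 100), 48, 48)
  sigma <- 2
  rad <- ceiling(4 * sigma)
  k1 <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  expect_equal(gaussian_denoise(img, sigma), oracle_conv_reflect(img, kern),
               tolerance = 1e-8)
})

test_that("the Gaussian filter is linear", {
  set.seed(3)
  i1 <- matrix(rnorm(400, 50, 5), 20, 20)
  i2 <- matrix(rnorm(400, 20, 5), 20, 20)
  lhs <- gaussian_denoise(2.5 * i1 + 4 * i2, 1.5)
  rhs <- 2.5 * gaussian_denoise(i1, 1.5) + 4 * gaussian_denoise(i2, 1.5)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("non-positive sigma is rejected", {
  expect_error(gaussian_denoise(matrix(1, 5, 5), 0),
               class = "wavetrack_validation_error")
})

test_that("phase congruency stays in [0,1] across varied inputs", {
  set.seed(6)
  imgs <- list(
    matrix(5, 32, 32),
    matrix(runif(32 * 32, 0, 4095), 32, 32),
    matrix(rpois(64 * 48, 100), 64, 48),
    {m <- matrix(0, 32, 32); m[16, ] <- 100; m},
    {m <- matrix(100, 40, 40); m[1:20, ] <- 900; m}
  )
  for (img in imgs) {
    pc <- phase_congruency(img)
    expect_true(all(pc >= 0 & pc <= 1))
  }
})

test_that("a constant image has (near) zero phase congruency", {
  expect_lte(max(phase_congruency(matrix(7, 32, 32))), 0.05)
})

test_that("a noiseless 1-px ridge is localised on its planted row", {
  img <- matrix(10, 64, 64); img[37, ] <- 210
  pc <- phase_congruency(img)
  expect_equal(unname(which(pc == max(pc), arr.ind = TRUE)[1, 1]), 37L)
})

test_that("phase congruency is contrast invariant on ridge pixels", {
  img <- matrix(10, 64, 64); img[32, ] <- 110
  pc1 <- phase_congruency(img)
  pc3 <- phase_congruency(3 * img)
  expect_lt(mean(abs(pc1[32, ] - pc3[32, ])), 0.02)
})

test_that("a blank noisy image yields an empty feature map", {
  set.seed(12)
  img <- matrix(rpois(64 * 64, 100) + rnorm(64 * 64, 0, 5), 64, 64)
  fm <- make_feature_map(img)
  expect_equal(sum(fm$binary), 0)
})

test_that("two parallel disjoint ridges give exactly two components", {
  set.seed(13)
  img <- matrix(rpois(64 * 96, 100), 64, 96) * 1.0
  img[20, 10:85] <- img[20, 10:85] + 400
  img[45, 10:85] <- img[45, 10:85] + 400
  fm <- make_feature_map(img)
  lab <- label_components(fm$binary, 8)
  expect_equal(max(lab), 2L)
})

test_that("hillock and tip fall in one component on simulated frames", {
  sim <- quick_movie(seed = 2, duration_min = 30)
  gt <- sim$truth
  for (f in c(1, 8, 16)) {
    fm <- make_feature_map(get_frame(sim$stack, f))
    lab <- label_components(fm$binary, 8)
    h <- gt$seeds$hillock_point
    tip <- round(wavetrack:::backbone_at(gt$backbone, gt$L_um[f]) /
                   gt$pixel_size_um + 0.5)
    expect_gt(lab[h[1], h[2]], 0)
    expect_equal(lab[h[1], h[2]], lab[tip[1], tip[2]])
  }
})

test_that("binary maps cover the planted structure with few false positives", {
  # >= 95% of ground-truth backbone pixels (dilated by 1) covered; <= 5% of
  # binary pixels farther than 3 px from the planted structures (backbone,
  # soma blob, growth cone disc)
  cov_all <- c(); fp_all <- c()
  for (sd in 1:2) {
    sim <- quick_movie(seed = sd, duration_min = 20)
    gt <- sim$truth; px <- gt$pixel_size_um
    H <- gt$image_shape[1]; W <- gt$image_shape[2]
    for (f in seq(1, 11, by = 1)) {
      fm <- make_feature_map(get_frame(sim$stack, f))
      keep <- gt$backbone$arc <= gt$L_um[f]
      bpx <- unique(cbind(pmin(pmax(round(gt$backbone$r[keep] / px + 0.5), 1), H),
                          pmin(pmax(round(gt$backbone$c[keep] / px + 0.5), 1), W)))
      hit <- vapply(seq_len(nrow(bpx)), function(i) {
        r <- bpx[i, 1]; c <- bpx[i, 2]
        any(fm$binary[max(1, r - 1):min(H, r + 1),
                      max(1, c - 1):min(W, c + 1)])
      }, logical(1))
      cov_all <- c(cov_all, mean(hit))
      truth_mask <- matrix(FALSE, H, W)
      truth_mask[bpx] <- TRUE
      rr <- row(truth_mask); cc <- col(truth_mask)
      sc <- gt$soma_centroid_px
      truth_mask <- truth_mask |
        ((rr - sc[1])^2 + (cc - sc[2])^2 <=
           (3 * gt$params$soma_sigma_um / px)^2)
      tip <- wavetrack:::backbone_at(gt$backbone, gt$L_um[f]) / px + 0.5
      rg <- sqrt(gt$gc_area_um2[f] / pi) / px
      truth_mask <- truth_mask |
        ((rr - tip[1])^2 + (cc - tip[2])^2 <= (rg + 1)^2)
      dil <- EBImage::imageData(EBImage::dilate(
        EBImage::Image(truth_mask * 1), EBImage::makeBrush(7, "disc"))) > 0
      fp_all <- c(fp_all, sum(fm$binary & !dil) / max(sum(fm$binary), 1))
    }
  }
  expect_gte(mean(cov_all), 0.95)
  expect_lte(mean(fp_all), 0.05)
})

test_that("pc parameter validation is strict", {
  expect_error(pc_params(pc_threshold = 0), class = "wavetrack_validation_error")
  expect_error(pc_params(min_wavelength = 1), class = "wavetrack_validation_error")
  expect_error(pc_params(epsilon = 0), class = "wavetrack_validation_error")
  expect_error(phase_congruency(matrix(1, 8, 8)),
               class = "wavetrack_validation_error")
})
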