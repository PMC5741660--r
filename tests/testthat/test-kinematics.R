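# Wave kinematics: velocity, transit rate, frequency, pulling events,
# elongation statistics and the frequency-velocity time course.

fake_trajectory <- function(time_s, L_um, s_um = NA, tracks = list()) {
  tr <- data.frame(frame = seq_along(time_s), time_s = time_s, L_um = L_um,
                   s_um = s_um, wave_present = !is.na(s_um))
  attr(tr, "wave_tracks") <- tracks
  class(tr) <- c("aw_trajectory", "data.frame")
  tr
}

test_that("wave velocity is distance over time", {
  expect_equal(wave_velocity(c(0, 480), c(10, 30)), 2.5)   # 20 um in 8 min
  expect_equal(wave_velocity(c(0, 60, 120), c(5, 5, 5)), 0)
  expect_error(wave_velocity(0, 10), class = "wavetrack_insufficient_data_error")
  expect_warning(wave_velocity(c(0, 60), c(10, 5)), "retrograde")
})

test_that("wave velocity is invariant to time shifts and linear resampling", {
  t0 <- c(0, 120, 240, 360); s0 <- 5 + 2.2 * t0 / 60
  v <- wave_velocity(t0, s0)
  expect_identical(wave_velocity(t0 + 981, s0), v)
  t_fine <- seq(0, 360, by = 10); s_fine <- 5 + 2.2 * t_fine / 60
  expect_equal(wave_velocity(t_fine, s_fine), v, tolerance = 1e-12)
})

test_that("normalised transit rate follows its definition", {
  full <- list(distance_um = 100, duration_min = 40, completed = TRUE)
  expect_equal(normalized_transit_rate(full, 100), 0.025)
  half <- list(distance_um = 50, duration_min = 40, completed = TRUE)
  expect_equal(normalized_transit_rate(half, 100), 0.0125)
  # equals velocity / L for full-length transits
  v <- full$distance_um / full$duration_min
  expect_equal(normalized_transit_rate(full, 100), v / 100)
  notyet <- list(distance_um = 50, duration_min = 40, completed = FALSE)
  out <- normalized_transit_rate(notyet, 100)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "incomplete")
})

test_that("wave frequency counts events per hour, optionally completed only", {
  ev <- data.frame(completed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(wave_frequency(ev, 2), 3.0)
  expect_equal(wave_frequency(ev, 2, complete_only = TRUE), 2.0)
  expect_error(wave_frequency(ev, 0), class = "wavetrack_validation_error")
})

test_that("the frequency estimator is unbiased on Poisson inception", {
  counts <- vapply(1:50, function(sd) {
    p <- sim_movie_params(duration_min = 120, rng_seed = 400 + sd)
    gt <- simulate_movie(p, render = FALSE)$truth
    ev <- wave_events(truth_trajectory(gt), min_frames = 2)
    nrow(ev)
  }, 1L)
  rate_hat <- mean(counts) / 2
  se <- sd(counts / 2) / sqrt(50)
  expect_lt(abs(rate_hat - 2.5), 3 * se)
})

test_that("pulling events honour the amplitude threshold and wave gating", {
  t <- seq(0, 3600, by = 60)
  # monotone growth, no waves -> empty
  tr <- fake_trajectory(t, 40 + t / 120)
  expect_equal(nrow(detect_pulling_events(tr)), 0)
  # a 2-um dip below the 5-um threshold -> empty
  L <- 40 + t / 120; L[30:35] <- L[30] - 2
  s <- rep(NA_real_, length(t)); s[25:40] <- L[25:40] - 10
  expect_equal(nrow(detect_pulling_events(fake_trajectory(t, L, s),
                                          min_amplitude_um = 5)), 0)
  # a 15-um retraction while the wave is within the window -> one event
  L2 <- 40 + t / 120; L2[31:36] <- L2[30] - seq(2.5, 15, by = 2.5)
  s2 <- rep(NA_real_, length(t)); s2[20:36] <- seq(10, L2[30] - 2,
                                                   length.out = 17)
  ev <- detect_pulling_events(fake_trajectory(t, L2, s2))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_um, 15, tolerance = 1e-9)
  # same retraction with the wave far away -> not a pulling event
  s3 <- rep(NA_real_, length(t)); s3[20:36] <- 2
  expect_equal(nrow(detect_pulling_events(fake_trajectory(t, L2, s3))), 0)
})

test_that("planted retractions are recovered from simulator trajectories", {
  # full planted retractions (close to the 15-um amplitude) must be detected;
  # amplitude accuracy is assessed on retractions not chained with another
  # merge, which a frame-pitch sampler cannot decompose
  hits <- 0; amps <- c(); n_planted <- 0
  for (sd in 1:5) {
    p <- sim_movie_params(duration_min = 120, frame_interval_s = 60,
                          rng_seed = 500 + sd)
    gt <- simulate_movie(p, render = FALSE)$truth
    ev <- detect_pulling_events(truth_trajectory(gt), min_amplitude_um = 5)
    full <- gt$waves$completed & !is.na(gt$waves$retraction_onset_min) &
      gt$waves$retraction_um >= 0.9 * p$gc_retraction_um
    planted <- gt$waves[full, ]
    n_planted <- n_planted + nrow(planted)
    for (i in seq_len(nrow(planted))) {
      ovl <- ev$onset_time_s <= planted$merge_time_min[i] * 60 &
        ev$end_time_s >= planted$retraction_onset_min[i] * 60
      if (any(ovl)) {
        hits <- hits + 1
        others <- gt$waves$merge_time_min[gt$waves$id != planted$id[i]]
        isolated <- !any(abs(others - planted$merge_time_min[i]) < 5,
                         na.rm = TRUE)
        if (isolated) {
          j <- which(ovl)[1]
          amps <- c(amps, abs(ev$amplitude_um[j] - planted$retraction_um[i]) /
                      planted$retraction_um[i])
        }
      }
    }
  }
  expect_gt(n_planted, 3)
  expect_equal(hits, n_planted)
  expect_lt(mean(amps), 0.2)
})

test_that("elongation anti-correlates with wave count on a planted cohort", {
  set.seed(31)
  trs <- lapply(1:20, function(i) {
    count <- sample(0:12, 1)
    elong <- 400 - 20 * count + rnorm(1, 0, 10)
    tracks <- replicate(count, data.frame(frame = 1:3, time_s = c(0, 60, 120),
                                          s_um = c(1, 2, 3), L_um = 50),
                        simplify = FALSE)
    fake_trajectory(c(0, 28800), c(40, 40 + elong), tracks = tracks)
  })
  res <- elongation_vs_wave_count(trs)
  expect_lt(res$rho, -0.9)
  expect_lt(res$p_value, 0.01)
  # identical elongations -> undefined correlation flag
  trs2 <- lapply(1:5, function(i) fake_trajectory(c(0, 100), c(40, 60)))
  expect_true(elongation_vs_wave_count(trs2)$undefined)
  expect_error(elongation_vs_wave_count(trs2[1:2]),
               class = "wavetrack_insufficient_data_error")
})

test_that("windowed frequency and velocity anti-correlate under planted alternation", {
  # alternating hour-long epochs: wave-free growth at 2.5 um/min, then
  # wave-rich growth at 0.5 um/min (three waves per slow epoch)
  t <- seq(0, 6 * 3600, by = 120)
  speed <- ifelse((t %/% 3600) %% 2 == 0, 2.5, 0.5)
  L <- 40 + cumsum(c(0, diff(t) / 60 * speed[-1]))
  tracks <- list()
  for (ep in which(unique(t %/% 3600) %% 2 == 1)) {
    for (k in 1:3) {
      t0 <- (ep - 1) * 3600 + (k - 1) * 1100
      tracks[[length(tracks) + 1]] <-
        data.frame(frame = 1:4, time_s = t0 + c(0, 120, 240, 360),
                   s_um = c(5, 9, 13, 17), L_um = NA)
    }
  }
  tr <- fake_trajectory(t, L, tracks = tracks)
  res <- frequency_velocity_timecourse(tr, window_min = 60)
  expect_lt(res$correlation, -0.5)
  # constant growth, no waves: frequency identically zero, flagged undefined
  tr0 <- fake_trajectory(t, L)
  res0 <- frequency_velocity_timecourse(tr0, window_min = 60)
  expect_true(res0$undefined)
  expect_true(all(res0$series$frequency_per_h == 0))
  expect_error(frequency_velocity_timecourse(tr, window_min = 1e5),
               class = "wavetrack_insufficient_data_error")
})

test_that("kinematics summary aggregates events, frequency and pulling", {
  p <- sim_movie_params(duration_min = 90, frame_interval_s = 60,
                        wave_times_min = c(5, 45), rng_seed = 9)
  gt <- simulate_movie(p, render = FALSE)$truth
  s <- summarize_kinematics(truth_trajectory(gt))
  expect_equal(s$n_waves, 2)
  expect_equal(s$frequency_per_h, 2 / 1.5)
  expect_equal(s$velocity_mean, mean(s$events$velocity_um_min))
  expect_gte(nrow(s$pulling_events), 1)
})
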