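test_that("track velocity follows unit arithmetic and closed forms", {
  expect_equal(track_velocity(track(c(0, 30, 60), c(1, 1, 1), c(2, 2, 2))), 0,
               ignore_attr = TRUE)

  # one 0.5 um step per 30 s frame -> 1.0 um/min
  trk <- track((0:10) * 30, (0:10) * 0.5, rep(0, 11))
  expect_equal(track_velocity(trk), 1.0, ignore_attr = TRUE)

  # uniform circular motion: speed = 2 r sin(theta/2) / dt * 60
  r <- 5; theta <- pi / 6; dt <- 10
  ang <- (0:12) * theta
  circ <- track((0:12) * dt, r * cos(ang), r * sin(ang))
  expect_equal(track_velocity(circ), 2 * r * sin(theta / 2) / dt * 60,
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(track(c(0, 0, 1), 1:3, 1:3), "strictly increasing")
})

test_that("track velocity is invariant to rigid motion and linear in scale", {
  trk <- simulate_track(30, 8, interval = 30, persistence = 0.4, seed = 6)
  v <- track_velocity(trk)
  th <- 0.7
  rot <- track(trk$time_s,
               cos(th) * trk$x_um - sin(th) * trk$y_um + 13,
               sin(th) * trk$x_um + cos(th) * trk$y_um - 4)
  expect_equal(track_velocity(rot), v, tolerance = 1e-9, ignore_attr = TRUE)
  scaled <- track(trk$time_s, 2 * trk$x_um, 2 * trk$y_um)
  expect_equal(as.numeric(track_velocity(scaled)), 2 * as.numeric(v),
               tolerance = 1e-9)
})

sim_punctum <- function(mode, seed, noise_sigma, amplitude = 150,
                        duration_frames = 60L) {
  cfg <- sim_config(grid_shape = c(64L, 64L), n_frames = duration_frames,
                    seed = seed, noise_sigma = noise_sigma,
                    channels = list(channel_spec("actin")))
  ev <- event_spec("photoconversion", time = 1, center = c(32, 14),
                   mode = mode, amplitude = amplitude, channel = "actin")
  sim <- simulate_wave_movie(cfg, list(ev))
  trk <- track_punctum(sim$stack, "converted", start = c(32, 14),
                       start_time = 1)
  punctum_displacement_test(trk, cfg$speed, sim$truth$punctum[[1]]$direction,
                            cfg$pixel_size)
}

test_that("noiseless puncta are classified without error in both modes", {
  vs <- sim_punctum("stationary", seed = 1, noise_sigma = 0)
  expect_equal(vs$classification, "stationary")
  va <- sim_punctum("advected", seed = 1, noise_sigma = 0)
  expect_equal(va$classification, "advected")
  # advected displacement ~ v * duration
  expect_equal(va$along_wave_um, va$expected_advection_um, tolerance = 0.15)
  expect_lte(va$total_displacement_um, va$path_length_um + 1e-9)
})

test_that("puncta at amplitude/noise 3 are classified correctly in >= 95% of runs", {
  correct <- 0
  for (mode in c("stationary", "advected")) {
    for (s in 1:10) {
      v <- sim_punctum(mode, seed = s, noise_sigma = 50, amplitude = 150)
      if (v$classification == mode) correct <- correct + 1
    }
  }
  expect_gte(correct / 20, 0.95)
})

test_that("FRAP fits recover injected mobile fraction and rate", {
  tr <- simulate_frap_trace(mobile_fraction = 0.8, rate_k = 0.1,
                            bleach_time = 20, duration = 140,
                            noise_sd = 0.01, seed = 3)
  fr <- frap_recovery(tr, 20)
  expect_equal(fr$mobile_fraction, 0.8, tolerance = 0.05 / 0.8)
  expect_equal(fr$rate_k, 0.1, tolerance = 0.10)
  expect_equal(fr$half_time, log(2) / fr$rate_k)
  expect_lt(fr$residual_rms, 0.05)
})

test_that("FRAP edge cases: no recovery, no bleach, instantaneous recovery", {
  tt <- seq(0, 60, by = 0.2)
  flat <- ifelse(tt < 20, 1, 0.1)
  fr <- frap_recovery(roi_trace(tt, flat + rnorm(length(tt), 0, 1e-3)), 20)
  expect_lt(abs(fr$mobile_fraction), 0.05)

  nb <- roi_trace(tt, rep(1, length(tt)) + rnorm(length(tt), 0, 1e-4))
  expect_error(frap_recovery(nb, 20), "no bleach")

  inst <- ifelse(tt < 20, 1, ifelse(tt < 20.2, 0.05, 1))
  fri <- frap_recovery(roi_trace(tt, inst), 20)
  expect_gt(fri$mobile_fraction, 0.9)
  expect_equal(fri$flag, "rate_at_bound")

  expect_error(frap_recovery(roi_trace(tt, flat), 0.6), "pre-bleach")
})

test_that("FRAP recovery is unbiased across the parameter grid", {
  for (M in c(0.3, 0.6, 0.9)) {
    for (k in c(0.05, 0.2)) {
      est <- sapply(1:5, function(s) {
        tr <- simulate_frap_trace(M, k, bleach_time = 20, duration = 140,
                                  noise_sd = 0.01, seed = s)
        fr <- frap_recovery(tr, 20)
        c(fr$mobile_fraction, fr$rate_k)
      })
      expect_lt(abs(mean(est[1, ]) - M), 0.02)
      expect_lt(abs(mean(est[2, ]) - k) / k, 0.05)
    }
  }
})
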