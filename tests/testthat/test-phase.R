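test_that("cross-correlation recovers constructed and closed-form shifts", {
  tt <- (0:599) * 0.2
  set.seed(9)
  x <- as.numeric(arima.sim(list(ar = 0.9), 620))
  ref <- roi_trace(tt, x[1:600])
  expect_equal(cross_correlation(ref, ref, search_halfwidth = 5)$lag, 0)
  expect_equal(cross_correlation(ref, ref, search_halfwidth = 5)$peak_correlation, 1)

  # probe delayed by exactly 3 frames
  probe <- roi_trace(tt, c(rep(x[1], 3), x[1:597]))
  le <- cross_correlation(probe, ref, search_halfwidth = 5)
  expect_equal(le$lag, 0.6, tolerance = 0.05)

  # sine shifted by 5 s
  ref_s <- roi_trace(tt, sin(2 * pi * tt / 20))
  pro_s <- roi_trace(tt, sin(2 * pi * (tt - 5) / 20))
  le_s <- cross_correlation(pro_s, ref_s, search_halfwidth = 12)
  expect_equal(le_s$lag, 5.0, tolerance = 0.1)

  expect_error(cross_correlation(roi_trace(tt, rep(1, 600)), ref), "constant")
})

test_that("discrete correlation values equal a brute-force shift-sum oracle", {
  set.seed(10)
  a <- rnorm(64); b <- rnorm(64)
  for (shift in c(-7, -1, 0, 2, 9)) {
    expect_equal(cortexwave:::shifted_correlation(a, b, shift),
                 brute_shift_cor(a, b, shift), tolerance = 1e-9)
  }
})

test_that("lag estimation is antisymmetric in the pair", {
  for (s in 1:5) {
    trs <- sim_pair(delta = -2.5, seed = s)
    dp <- detrend_normalize(trs$probe); dr <- detrend_normalize(trs$ref)
    l1 <- cross_correlation(dp, dr, period = 20)$lag
    l2 <- cross_correlation(dr, dp, period = 20)$lag
    expect_equal(l1, -l2, tolerance = 0.1)
  }
})

test_that("cycle peaks are found at construction times on noiseless pulse trains", {
  pt <- pulse_train_trace(duration = 120, noise_sd = 0)
  cl <- call_wave(pt$trace)
  det <- attr(cl, "detrended_trace")
  peaks <- detect_cycles(det, cl, refine = FALSE)
  expect_length(peaks, length(pt$centers))
  # interior peaks exact; the outermost two may shift one frame from the
  # partial-window detrending at the trace edges
  expect_equal(peaks[2:5], pt$centers[2:5])
  expect_lt(max(abs(peaks - pt$centers)), 0.2 + 1e-9)

  # adding a constant offset changes nothing (detrending contract)
  tr2 <- roi_trace(pt$trace$times, pt$trace$values + 500)
  cl2 <- call_wave(tr2)
  expect_equal(detect_cycles(attr(cl2, "detrended_trace"), cl2, refine = FALSE),
               peaks)
})

test_that("cycle peaks are recovered within one frame at amplitude/noise 5", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    trs <- sim_pair(delta = 0, seed = s)                    # noise sigma 20
    cfg0 <- sim_config(grid_shape = c(24L, 24L), n_frames = 600L,
                       channels = list(channel_spec("ref")), noise_sigma = 0)
    ref0 <- simulate_traces(cfg0, roi(2L, 2L, 20L, 20L))$ref
    cl0 <- call_wave(ref0)
    truth <- detect_cycles(attr(cl0, "detrended_trace"), cl0)
    cl <- call_wave(trs$ref)
    expect_true(cl$is_wave)
    peaks <- detect_cycles(attr(cl, "detrended_trace"), cl)
    for (cc in truth) {
      total <- total + 1
      if (any(abs(peaks - cc) <= 0.2 + 1e-9)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("average profiles reproduce the waveform and count cycles", {
  # periodic probe sampled without noise: profile is one exact cycle
  tt <- seq(0, 240, by = 0.2)
  v <- cortexwave:::wave_pulse((tt - 10) / 20, 0.5)
  probe <- roi_trace(tt, v)
  peaks <- seq(10, 230, by = 20)
  prof <- average_profile(probe, peaks, window = 20)
  expect_equal(prof$n_cycles, sum(peaks >= 10 & peaks <= 230))
  expect_lt(max(prof$sd), 1e-9)
  expect_equal(prof$rel_times[which.max(prof$mean)], 0)
  # the mean profile is the waveform itself around its peak
  expect_equal(prof$mean, cortexwave:::wave_pulse(prof$rel_times / 20, 0.5),
               tolerance = 1e-9)

  expect_error(average_profile(probe, peaks[1:2], window = 20), "at least 3")
})

test_that("profiles locate injected probe offsets", {
  for (s in 1:3) {
    trs <- sim_pair(delta = -3, seed = s)
    dr <- detrend_normalize(trs$ref); dp <- detrend_normalize(trs$probe)
    cl <- call_wave(trs$ref)
    peaks <- detect_cycles(dr, cl)
    prof <- average_profile(dp, peaks, window = 20)
    expect_equal(prof$rel_times[which.max(prof$mean)], -3, tolerance = 0.5 / 3)
    pl <- profile_lag(prof)
    expect_equal(pl$status, "ok")
    expect_equal(pl$lag, -3, tolerance = 0.15 / 3)
  }
})

test_that("profile lags agree with cross-correlation and resolve degenerate input", {
  for (s in 1:5) {
    trs <- sim_pair(delta = 1, seed = s)
    dr <- detrend_normalize(trs$ref); dp <- detrend_normalize(trs$probe)
    le <- cross_correlation(dp, dr, period = 20)
    peaks <- detect_cycles(dr, call_wave(trs$ref))
    pl <- profile_lag(average_profile(dp, peaks, window = 20))
    expect_lt(abs(le$lag - pl$lag), 0.2)  # within one frame
  }
  flat <- structure(list(rel_times = seq(-5, 5, 0.2),
                         mean = rep(1, 51), sd = rep(0, 51), n_cycles = 4),
                    class = "average_profile")
  expect_equal(profile_lag(flat)$status, "unresolved")
})

test_that("asymmetry index matches constructed waveform geometry", {
  # symmetric triangle -> 1
  u <- seq(-10, 10 - 0.2, by = 0.2)
  tri <- 1 - abs(u) / 10
  prof <- structure(list(rel_times = u, mean = tri, sd = tri * 0,
                         n_cycles = 5), class = "average_profile")
  expect_equal(asymmetry_index(prof)$index, 1, tolerance = 0.05)

  # sawtooth rising over 75% of the cycle -> 3
  saw <- cortexwave:::wave_pulse(seq(0, 1 - 0.01, by = 0.01), 0.75)
  prof2 <- structure(list(rel_times = seq(-10, 10 - 0.2, by = 0.2),
                          mean = saw, sd = saw * 0, n_cycles = 5),
                     class = "average_profile")
  a <- asymmetry_index(prof2)
  expect_equal(a$index, 3, tolerance = 0.1)

  # slow-assembly simulation scores above 1
  trs <- sim_pair(delta = 0, seed = 2, rise = 0.75)
  dr <- detrend_normalize(trs$ref)
  cl <- call_wave(trs$ref)
  prof3 <- average_profile(detrend_normalize(trs$probe),
                           detect_cycles(dr, cl), window = 20)
  expect_gt(asymmetry_index(prof3)$index, 1)
})

test_that("anti-phase scoring flags inverted pairs and passes identical ones", {
  tt <- (0:599) * 0.2
  base <- sin(2 * pi * tt / 20)
  ref <- detrend_normalize(roi_trace(tt, 100 + 30 * base))
  inv <- detrend_normalize(roi_trace(tt, 100 - 30 * base))
  aps <- anti_phase_score(inv, ref)
  expect_equal(aps$zero_lag_correlation, -1, tolerance = 1e-6)
  expect_equal(aps$lag_fraction, 0.5, tolerance = 0.02)
  expect_true(aps$anti_phase)

  same <- anti_phase_score(ref, ref)
  expect_equal(same$zero_lag_correlation, 1, tolerance = 1e-9)
  expect_lt(same$lag_fraction, 0.02)
  expect_false(same$anti_phase)

  short <- detrend_normalize(roi_trace(tt, 100 + 30 * sin(2 * pi * tt / 10)))
  expect_error(anti_phase_score(short, ref), "periods differ")
})

test_that("simulated tubulin channels are flagged anti-phase against actin", {
  flagged <- 0
  for (s in 1:20) {
    trs <- sim_pair(delta = 0, seed = s, anti = TRUE)
    aps <- anti_phase_score(trs$probe, trs$ref)
    if (aps$anti_phase) flagged <- flagged + 1
  }
  expect_gte(flagged, 19)
})
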