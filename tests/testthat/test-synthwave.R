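test_that("channels with identical parameters render identically after normalization", {
  cfg <- sim_config(grid_shape = c(16L, 16L), n_frames = 120L, seed = 7,
                    channels = list(channel_spec("a", baseline = 50, amplitude = 30),
                                    channel_spec("b", baseline = 200, amplitude = 90)),
                    noise_sigma = 0)
  sim <- simulate_wave_movie(cfg)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(mm(sim$stack$data[1, , , ]), mm(sim$stack$data[2, , , ]),
               tolerance = 1e-12)
})

test_that("a noiseless pixel trace is exactly periodic with period T", {
  cfg <- sim_config(grid_shape = c(8L, 8L), n_frames = 600L, period = 20,
                    frame_interval = 0.2, noise_sigma = 0,
                    channels = list(channel_spec("a")))
  sim <- simulate_wave_movie(cfg)
  v <- sim$stack$data[1, , 5, 5]
  expect_equal(v[1:500], v[101:600], tolerance = 1e-12)  # shift of 100 frames
  # overlap-normalized autocorrelation peaks at one full period
  ac <- vapply(1:150, function(k) cortexwave:::shifted_correlation(v, v, k),
               numeric(1))
  expect_equal(which.max(ac), 100L)
  expect_equal(ac[100], 1, tolerance = 1e-12)
})

test_that("movies are deterministic in the seed and vary across seeds", {
  cfg <- sim_config(grid_shape = c(8L, 8L), n_frames = 40L, seed = 3,
                    channels = list(channel_spec("a")), noise_sigma = 10)
  s1 <- simulate_wave_movie(cfg)$stack$data
  s2 <- simulate_wave_movie(cfg)$stack$data
  expect_identical(s1, s2)
  cfg2 <- sim_config(grid_shape = c(8L, 8L), n_frames = 40L, seed = 4,
                     channels = list(channel_spec("a")), noise_sigma = 10)
  expect_false(identical(s1, simulate_wave_movie(cfg2)$stack$data))
})

test_that("invalid configurations and events are rejected with clear errors", {
  expect_error(sim_config(period = 0.3, frame_interval = 0.2), "Nyquist")
  expect_error(sim_config(grid_shape = c(4L, 16L)), "grid_shape")
  expect_error(channel_spec("a", rise_fraction = 1), "rise_fraction")
  expect_error(sim_config(channels = list(channel_spec("a", phase_offset = 12))),
               "phase_offset")
  cfg <- sim_config(grid_shape = c(16L, 16L), n_frames = 20L,
                    channels = list(channel_spec("a")))
  ev_out <- event_spec("photoconversion", time = 1, center = c(40, 8))
  expect_error(simulate_wave_movie(cfg, list(ev_out)), "outside the grid")
  ev_late <- event_spec("photoconversion", time = 1e4, center = c(8, 8))
  expect_error(simulate_wave_movie(cfg, list(ev_late)), "span")
})

test_that("mean intensity over one period is B + A/2 regardless of phase offset", {
  # conservation: the asymmetric pulse has mean 1/2 whatever delta does
  for (delta in c(-4, 0, 3)) {
    cfg <- sim_config(grid_shape = c(8L, 8L), n_frames = 100L, period = 20,
                      frame_interval = 0.2, noise_sigma = 0,
                      channels = list(channel_spec("a", baseline = 100,
                                                   amplitude = 60,
                                                   phase_offset = delta)))
    sim <- simulate_wave_movie(cfg)
    expect_equal(mean(sim$stack$data[1, , 3, 6]), 100 + 30,
                 tolerance = 0.2)
  }
})

test_that("simulate_traces recovers injected lag and degenerate cases", {
  trs <- sim_pair(delta = 2.0, seed = 1, noise_sigma = 0)
  le <- cross_correlation(detrend_normalize(trs$probe),
                          detrend_normalize(trs$ref), period = 20)
  expect_lt(abs(le$lag - 2.0), 0.1)  # within half a frame

  trs <- sim_pair(delta = 0, seed = 1, noise_sigma = 0, anti = TRUE)
  expect_lt(cor(trs$probe$values, trs$ref$values), 0)

  cfg <- sim_config(grid_shape = c(24L, 24L), n_frames = 100L, noise_sigma = 0,
                    channels = list(channel_spec("flat", baseline = 42,
                                                 amplitude = 0)))
  tr <- simulate_traces(cfg)$flat
  expect_equal(tr$values, rep(42, 100))
})

test_that("simulate_traces matches the rendered movie at the same ROI", {
  cfg <- sim_config(grid_shape = c(24L, 24L), n_frames = 80L, seed = 5,
                    channels = list(channel_spec("a")), noise_sigma = 0)
  r <- roi(2L, 2L, 20L, 20L)
  fast <- simulate_traces(cfg, r)$a
  sim <- simulate_wave_movie(cfg)
  slow <- extract_roi_trace(sim$stack, r, "a")
  expect_equal(fast$values, slow$values, tolerance = 1e-12)
  expect_equal(fast$times, slow$times)
})

test_that("simulated tracks honour speed, persistence and the random-walk limit", {
  trk0 <- simulate_track(10, step_speed = 0, interval = 30)
  expect_equal(max(abs(trk0$x_um)), 0)
  expect_equal(track_velocity(trk0), 0, ignore_attr = TRUE)

  trk1 <- simulate_track(50, step_speed = 12, interval = 30, persistence = 1,
                         seed = 2)
  expect_equal(track_velocity(trk1), 12, tolerance = 1e-9, ignore_attr = TRUE)
  # straight line: net displacement equals path length
  expect_equal(attr(track_velocity(trk1), "net_velocity"), 12, tolerance = 1e-9)

  trk <- simulate_track(1000, step_speed = 12, interval = 30, persistence = 0,
                        seed = 11)
  path <- 1000 * 12 * 30 / 60
  net <- sqrt(trk$x_um[1001]^2 + trk$y_um[1001]^2)
  expect_lt(net, 0.15 * path)
})

test_that("ground truth serializes to JSON and back losslessly", {
  cfg <- sim_config(grid_shape = c(32L, 32L), n_frames = 40L, seed = 9,
                    channels = list(channel_spec("a"),
                                    channel_spec("tub", anti_phase = TRUE)))
  ev <- event_spec("photoconversion", time = 2, center = c(16, 8),
                   mode = "advected", channel = "a")
  sim <- simulate_wave_movie(cfg, list(ev))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  rt <- read_ground_truth(path)
  expect_equal(rt$true_period, sim$truth$true_period)
  expect_equal(rt$channels[[2]]$anti_phase, TRUE)
  expect_equal(rt$channels[[1]]$true_lag, 0)
  expect_equal(rt$punctum[[1]]$mode, "advected")
  expect_equal(rt$punctum[[1]]$trajectory$row, sim$truth$punctum[[1]]$trajectory$row,
               tolerance = 1e-12)
})
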