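const_stack <- function(value = 7, frames = 5L) {
  movie_stack(array(value, dim = c(1, frames, 12, 12)), "a", 0.16, 0.2)
}

test_that("ROI traces are arithmetic means with calibrated times", {
  expect_equal(extract_roi_trace(const_stack(), roi(2L, 2L, 4L, 4L), "a")$values,
               rep(7, 5))
  st <- const_stack()
  st$data[1, 1, 3:4, 3:4] <- matrix(c(1, 3, 2, 4), 2)
  tr <- extract_roi_trace(st, roi(2L, 2L, 2L, 2L), "a")
  expect_equal(tr$values[1], 2.5)
  expect_equal(tr$times, (0:4) * 0.2)
  expect_error(extract_roi_trace(st, roi(8L, 8L, 8L, 8L), "a"), "bounds")
  expect_error(extract_roi_trace(st, roi(0L, 0L, 2L, 2L), "nope"), "unknown channel")
})

test_that("ROI extraction is linear in the stack", {
  set.seed(3)
  x <- array(rnorm(2 * 4 * 10 * 10), dim = c(2, 4, 10, 10))[1, , , , drop = FALSE]
  y <- array(rnorm(1 * 4 * 10 * 10), dim = c(1, 4, 10, 10))
  mk <- function(d) movie_stack(d, "a", 0.1, 0.5)
  r <- roi(1L, 1L, 5L, 5L)
  ta <- extract_roi_trace(mk(x), r, "a")$values
  tb <- extract_roi_trace(mk(y), r, "a")$values
  tc <- extract_roi_trace(mk(2 * x - 3 * y), r, "a")$values
  expect_equal(tc, 2 * ta - 3 * tb, tolerance = 1e-12)
})

test_that("kymographs reslice correctly and respect symmetry", {
  # static scene: every kymograph row identical
  st <- const_stack()
  st$data[1, , , ] <- aperm(array(seq_len(144), dim = c(12, 12, 5)), c(3, 1, 2))
  km <- make_kymograph(st, line_spec(c(5, 1), c(5, 10)), "a")
  expect_equal(nrow(km$data), 5)
  for (i in 2:5) expect_equal(km$data[i, ], km$data[1, ])

  # planar wave constant perpendicular to the line: width 1 vs 3 identical
  cfg <- sim_config(grid_shape = c(16L, 40L), n_frames = 30L, noise_sigma = 0,
                    channels = list(channel_spec("a")))
  sim <- simulate_wave_movie(cfg)
  k1 <- make_kymograph(sim$stack, line_spec(c(8, 2), c(8, 37), 1L), "a")
  k3 <- make_kymograph(sim$stack, line_spec(c(8, 2), c(8, 37), 3L), "a")
  expect_equal(k1$data, k3$data, tolerance = 1e-12)

  expect_error(line_spec(c(3, 3), c(3, 3)), "degenerate")
})

test_that("time projections encode motion as colour and stillness as gray", {
  st <- const_stack(frames = 10L)
  set.seed(4)
  frame <- matrix(runif(144, 10, 90), 12)
  for (i in 1:10) st$data[1, i, , ] <- frame
  pr <- time_projection(st, "a", t0 = 0, interval = 0.4)
  expect_equal(pr[, , 1], pr[, , 2], tolerance = 1e-12)
  expect_equal(pr[, , 2], pr[, , 3], tolerance = 1e-12)

  pr0 <- time_projection(st, "a", t0 = 1, interval = 0)
  expect_equal(pr0[, , 1], pr0[, , 3], tolerance = 1e-12)

  cfg <- sim_config(grid_shape = c(24L, 48L), n_frames = 60L, noise_sigma = 0,
                    channels = list(channel_spec("a")))
  sim <- simulate_wave_movie(cfg)
  prw <- time_projection(sim$stack, "a", t0 = 0, interval = 4)
  expect_gt(max(abs(prw[, , 1] - prw[, , 3])), 0.5)  # bands moved

  expect_error(time_projection(st, "a", t0 = 1.6, interval = 0.4), "span")
})

test_that("wave speed is recovered within 10% across speeds", {
  for (v in c(0.2, 0.5, 1.0)) {
    for (s in 1:2) {
      cfg <- sim_config(grid_shape = c(16L, 260L), n_frames = 150L, seed = s,
                        speed = v, channels = list(channel_spec("a")),
                        noise_sigma = 20)
      km <- make_kymograph(simulate_wave_movie(cfg)$stack,
                           line_spec(c(8, 2), c(8, 257), 3L), "a")
      est <- estimate_wave_speed(km)
      expect_equal(est$status, "ok")
      expect_lt(abs(est$speed - v) / v, 0.10)
    }
  }
})

test_that("static or incoherent kymographs are reported undetermined", {
  st <- const_stack(frames = 60L)
  set.seed(5)
  frame <- matrix(runif(144), 12)
  for (i in 1:60) st$data[1, i, , ] <- frame   # static stripes in time
  km <- make_kymograph(st, line_spec(c(5, 1), c(5, 10)), "a")
  expect_equal(estimate_wave_speed(km)$status, "undetermined")

  km$data <- matrix(rnorm(60 * 80), 60, 80)    # pure noise
  expect_equal(estimate_wave_speed(km)$status, "undetermined")
})

test_that("subsampling time at twice the interval leaves the speed unchanged", {
  cfg <- sim_config(grid_shape = c(16L, 260L), n_frames = 150L, seed = 1,
                    speed = 0.5, channels = list(channel_spec("a")),
                    noise_sigma = 0)
  km <- make_kymograph(simulate_wave_movie(cfg)$stack,
                       line_spec(c(8, 2), c(8, 257), 1L), "a")
  km2 <- km
  km2$data <- km$data[seq(1, 150, by = 2), ]
  km2$frame_interval <- km$frame_interval * 2
  v1 <- estimate_wave_speed(km)$speed
  v2 <- estimate_wave_speed(km2)$speed
  expect_equal(v1, v2, tolerance = 0.05)
})
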