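# Independent oracles and small trace constructors used across tests.

# Brute-force O(N^2) DFT power with the same one-sided scaling contract as
# periodogram(): sum over the returned vector equals sum of squared centered
# values. Written from the DFT definition, independent of stats::fft.
brute_dft_power <- function(x, dt) {
  n <- length(x)
  x <- x - mean(x)
  nf <- floor(n / 2) + 1L
  p <- numeric(nf)
  j <- 0:(n - 1)
  for (k in seq_len(nf) - 1L) {
    re <- sum(x * cos(-2 * pi * j * k / n))
    im <- sum(x * sin(-2 * pi * j * k / n))
    p[k + 1L] <- (re^2 + im^2) / n
  }
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(frequencies = (seq_len(nf) - 1L) / (n * dt), power = p * dbl)
}

# Brute-force overlap-restricted Pearson correlation at an integer shift,
# written as explicit sums over the overlap.
brute_shift_cor <- function(probe, reference, shift) {
  n <- length(probe)
  ia <- max(1, 1 + shift):min(n, n + shift)
  a <- probe[ia]
  b <- reference[ia - shift]
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Gaussian pulse train: clearly skewed waveform with flat baseline, for
# polarity and cycle-detection tests. Pulses centred at `centers`.
pulse_train_trace <- function(duration = 120, dt = 0.2, period = 20,
                              amp = 1, sigma = 3, baseline = 10,
                              invert = FALSE, noise_sd = 0, seed = 1,
                              first_peak = period / 2) {
  times <- seq(0, duration, by = dt)
  centers <- seq(first_peak, duration, by = period)
  v <- rep(baseline, length(times))
  for (cc in centers) v <- v + amp * exp(-(times - cc)^2 / (2 * sigma^2))
  if (invert) v <- 2 * baseline - v
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  list(trace = roi_trace(times, v), centers = centers)
}

# Small two-channel trace simulation under the standard study conditions
# (T = 20 s, 5 Hz, 20x20 px ROI, amplitude/noise = 5).
sim_pair <- function(delta, seed, noise_sigma = 20, n_frames = 600,
                     rise = 0.7, anti = FALSE) {
  cfg <- sim_config(grid_shape = c(24L, 24L), n_frames = n_frames, seed = seed,
                    channels = list(
                      channel_spec("ref"),
                      channel_spec("probe", phase_offset = delta,
                                   rise_fraction = rise, anti_phase = anti)),
                    noise_sigma = noise_sigma)
  simulate_traces(cfg, roi(2L, 2L, 20L, 20L))
}
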