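# Synthetic travelling-wave movie generator.
#
# Phenomenological model: each channel c reports
#   I_c(x, t) = B_c + A_c * w((t - delta_c - d(x)/v) / T)  (+ noise)
# where d(x) is the distance (um) from a point source (circular waves) or the
# signed coordinate along a propagation direction (planar waves), T the
# temporal period, v the propagation speed, delta_c a per-channel phase offset
# in seconds (negative = earlier than the zero-offset reference) and w an
# asymmetric periodic pulse in [0, 1]: a linear rise over `rise_fraction` of
# the period followed by a linear fall over the remainder, mimicking the
# slow-assembly / fast-disassembly waveforms of formin recruitment.
# Channels flagged `anti_phase` report B + A * (1 - w), emulating the tubulin
# signal whose density dips where the actin wave passes.

#' Channel specification for the wave simulator
#'
#' @param label channel name.
#' @param baseline baseline intensity B (AU).
#' @param amplitude modulation amplitude A (AU), >= 0.
#' @param phase_offset per-channel temporal offset delta in seconds; negative
#'   means the channel peaks *earlier* than a zero-offset channel.
#' @param rise_fraction fraction of the period spent rising (0 < r < 1);
#'   values above 0.5 give the characteristic gentle-rise/sharp-fall waveform.
#' @param anti_phase if `TRUE` the channel's modulation is inverted
#'   (tubulin-like: intensity dips where the wave passes).
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(label, baseline = 200, amplitude = 100,
                         phase_offset = 0, rise_fraction = 0.7,
                         anti_phase = FALSE) {
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (rise_fraction <= 0 || rise_fraction >= 1)
    stopf("rise_fraction must be in (0, 1)")
  structure(list(label = label, baseline = baseline, amplitude = amplitude,
                 phase_offset = phase_offset, rise_fraction = rise_fraction,
                 anti_phase = isTRUE(anti_phase)),
            class = "channel_spec")
}

#' Simulation configuration
#'
#' Defaults reflect a typical TIRF acquisition of cortical waves: 5 Hz
#' frame rate (0.2 s interval), 0.16 um pixels (16 um camera pixel behind a
#' 100x objective), a 20 s period, 0.5 um/s propagation, and a two-channel
#' reference/probe pair whose probe peaks 3.9 s before the reference.
#'
#' @param grid_shape (rows, cols) in pixels, each >= 8.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames.
#' @param period temporal period T in seconds; must exceed
#'   `2 * frame_interval` (Nyquist).
#' @param speed propagation speed v in um/s, > 0.
#' @param source either the string `"planar"` (plane wave travelling along
#'   `direction`) or a (row, col) pixel coordinate of a point source emitting
#'   circular waves.
#' @param direction propagation direction in radians (planar source only);
#'   0 propagates along increasing column.
#' @param channels list of [channel_spec()] objects.
#' @param noise_sigma Gaussian read-noise standard deviation (AU), >= 0.
#' @param shot_noise if `TRUE`, Poisson shot noise is applied to the
#'   noiseless signal before read noise is added.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   produce bit-identical movies.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(128L, 128L), pixel_size = 0.16,
                       frame_interval = 0.2, n_frames = 600L,
                       period = 20, speed = 0.5,
                       source = "planar", direction = 0,
                       channels = list(
                         channel_spec("FBP17"),
                         channel_spec("FHDC1", phase_offset = -3.9,
                                      rise_fraction = 0.75)),
                       noise_sigma = 20, shot_noise = FALSE, seed = 1L) {
  if (length(grid_shape) != 2L || any(grid_shape < 8))
    stopf("grid_shape must be two values >= 8")
  if (frame_interval <= 0) stopf("frame_interval must be > 0")
  if (period <= 2 * frame_interval)
    stopf("period (%.3g s) violates the Nyquist limit: must exceed 2 * frame_interval (%.3g s)",
          period, 2 * frame_interval)
  if (speed <= 0) stopf("speed must be > 0")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (!length(channels)) stopf("at least one channel is required")
  for (ch in channels) {
    if (!inherits(ch, "channel_spec")) stopf("channels must be channel_spec objects")
    if (abs(ch$phase_offset) >= period / 2)
      stopf("|phase_offset| of channel '%s' must be < period/2", ch$label)
  }
  planar <- identical(source, "planar")
  if (!planar && (length(source) != 2L || any(source < 0) ||
                  any(source > grid_shape - 1)))
    stopf("source must be \"planar\" or a (row, col) point inside the grid")
  structure(
    list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         period = period, speed = speed, source = source,
         direction = direction, channels = channels,
         noise_sigma = noise_sigma, shot_noise = isTRUE(shot_noise),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Photoconversion / FRAP event specification
#'
#' @param kind `"photoconversion"` or `"frap_bleach"`.
#' @param time event time in seconds.
#' @param center (row, col) pixel position (photoconversion spot centre).
#' @param radius Gaussian sigma of the converted punctum in pixels.
#' @param mode `"stationary"` (punctum stays put; de novo nucleation at the
#'   wave front) or `"advected"` (punctum rides the wave at speed v).
#' @param amplitude peak intensity of the converted punctum (AU).
#' @param box (row0, col0, height, width) bleach region, 0-based pixels
#'   (FRAP only).
#' @param channel label or index of the channel the event acts on; FRAP
#'   bleaches that channel, photoconversion adds a new `"converted"` channel.
#' @param bleach_depth fraction of intensity removed at bleach time (0-1].
#' @param mobile_fraction fraction of the bleached population that recovers.
#' @param rate_k recovery rate constant (1/s).
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(kind = c("photoconversion", "frap_bleach"), time,
                       center = NULL, radius = 2, mode = "stationary",
                       amplitude = 150, box = NULL, channel = 1L,
                       bleach_depth = 0.9, mobile_fraction = 0.8,
                       rate_k = 0.1) {
  kind <- match.arg(kind)
  if (kind == "photoconversion") {
    if (is.null(center) || length(center) != 2L)
      stopf("photoconversion needs a (row, col) center")
    if (!mode %in% c("stationary", "advected"))
      stopf("mode must be 'stationary' or 'advected'")
  } else {
    if (is.null(box) || length(box) != 4L)
      stopf("frap_bleach needs box = (row0, col0, height, width)")
    if (bleach_depth <= 0 || bleach_depth > 1) stopf("bleach_depth must be in (0, 1]")
    if (mobile_fraction < 0 || mobile_fraction > 1)
      stopf("mobile_fraction must be in [0, 1]")
    if (rate_k <= 0) stopf("rate_k must be > 0")
  }
  structure(list(kind = kind, time = time, center = center, radius = radius,
                 mode = mode, amplitude = amplitude, box = box,
                 channel = channel, bleach_depth = bleach_depth,
                 mobile_fraction = mobile_fraction, rate_k = rate_k),
            class = "event_spec")
}

## Periodic asymmetric pulse in [0, 1], peaked at integer phases: a linear
## rise over the last `rise` fraction of each cycle into the peak, then a
## linear fall over `1 - rise` after it. Anchoring the peak at phase zero
## makes a channel's phase_offset its peak-time lag irrespective of the
## waveform's rise fraction. Argument is phase in cycles (any real).
wave_pulse <- function(u, rise) {
  u <- u - floor(u)
  ifelse(u <= 1 - rise, 1 - u / (1 - rise), (u - (1 - rise)) / rise)
}

## Distance map in um: radial distance from a point source, or signed
## coordinate along the propagation direction for planar waves.
distance_map <- function(config) {
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  r <- matrix(0:(rows - 1), rows, cols)
  c <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
  if (identical(config$source, "planar")) {
    (c * cos(config$direction) + r * sin(config$direction)) * config$pixel_size
  } else {
    sqrt((r - config$source[1])^2 + (c - config$source[2])^2) * config$pixel_size
  }
}

## Unit propagation direction (row, col) at a pixel position.
propagation_direction <- function(config, at) {
  if (identical(config$source, "planar")) {
    c(sin(config$direction), cos(config$direction))
  } else {
    d <- c(at[1] - config$source[1], at[2] - config$source[2])
    n <- sqrt(sum(d^2))
    if (n == 0) c(0, 1) else d / n
  }
}

#' Simulate a multi-channel travelling-wave movie
#'
#' Renders the phenomenological wave model (see [sim_config()]) into a
#' [movie_stack()], optionally with photoconversion and FRAP events, and
#' returns the full ground truth used.
#'
#' @param config a [sim_config()].
#' @param events list of [event_spec()] objects.
#' @return list with elements `stack` ([movie_stack()]) and `truth`
#'   (class `sim_ground_truth`).
#' @export
simulate_wave_movie <- function(config, events = list()) {
  stopifnot(inherits(config, "sim_config"))
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  nfr <- config$n_frames; dt <- config$frame_interval
  span <- (nfr - 1) * dt
  for (ev in events) {
    if (!inherits(ev, "event_spec")) stopf("events must be event_spec objects")
    if (ev$time < 0 || ev$time > span)
      stopf("event at t = %.3g s lies outside the movie span [0, %.3g] s", ev$time, span)
    if (ev$kind == "photoconversion") {
      if (any(ev$center < 0) || ev$center[1] > rows - 1 || ev$center[2] > cols - 1)
        stopf("photoconversion center outside the grid")
    } else {
      if (any(ev$box[1:2] < 0) || ev$box[1] + ev$box[3] > rows ||
          ev$box[2] + ev$box[4] > cols)
        stopf("FRAP box outside the grid")
    }
  }

  d <- distance_map(config)
  times <- (seq_len(nfr) - 1) * dt
  nch <- length(config$channels)
  pc_events <- Filter(function(e) e$kind == "photoconversion", events)
  frap_events <- Filter(function(e) e$kind == "frap_bleach", events)
  labels <- vapply(config$channels, `[[`, "", "label")
  n_out <- nch + length(pc_events)
  data <- array(0, dim = c(n_out, nfr, rows, cols))

  truth_punctum <- list()
  truth_frap <- list()

  with_seed(config$seed, {
    for (ci in seq_len(nch)) {
      ch <- config$channels[[ci]]
      phase0 <- -d / (config$speed * config$period)   # spatial phase, cycles
      for (fi in seq_len(nfr)) {
        u <- (times[fi] - ch$phase_offset) / config$period + phase0
        w <- wave_pulse(u, ch$rise_fraction)
        if (ch$anti_phase) w <- 1 - w
        clean <- ch$baseline + ch$amplitude * w
        for (ev in frap_events) {
          if (channel_index_label(labels, ev$channel) == ci && times[fi] >= ev$time) {
            f <- (1 - ev$bleach_depth) + ev$bleach_depth * ev$mobile_fraction *
              (1 - exp(-ev$rate_k * (times[fi] - ev$time)))
            b <- ev$box
            clean[(b[1] + 1):(b[1] + b[3]), (b[2] + 1):(b[2] + b[4])] <-
              clean[(b[1] + 1):(b[1] + b[3]), (b[2] + 1):(b[2] + b[4])] * f
          }
        }
        data[ci, fi, , ] <- apply_noise(clean, config)
      }
    }
    # photoconverted puncta render into their own appended channel: the
    # converted fluorophore is spectrally separate from the parent channel
    for (ei in seq_along(pc_events)) {
      ev <- pc_events[[ei]]
      ci <- nch + ei
      src_ch <- config$channels[[channel_index_label(labels, ev$channel)]]
      dir <- propagation_direction(config, ev$center)
      traj <- matrix(NA_real_, nfr, 2)
      rgrid <- matrix(0:(rows - 1), rows, cols)
      cgrid <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
      for (fi in seq_len(nfr)) {
        t <- times[fi]
        clean <- matrix(0, rows, cols)
        if (t >= ev$time) {
          pos <- ev$center
          if (ev$mode == "advected") {
            pos <- pos + dir * config$speed * (t - ev$time) / config$pixel_size
          }
          traj[fi, ] <- pos
          # punctum brightness follows the local wave envelope but never
          # fully vanishes, as converted fluorophores remain visible
          d_pos <- if (identical(config$source, "planar")) {
            (pos[2] * cos(config$direction) + pos[1] * sin(config$direction)) *
              config$pixel_size
          } else {
            sqrt(sum((pos - config$source)^2)) * config$pixel_size
          }
          u <- (t - src_ch$phase_offset - d_pos / config$speed) / config$period
          mod <- (1 + wave_pulse(u, src_ch$rise_fraction)) / 2
          clean <- ev$amplitude * mod *
            exp(-((rgrid - pos[1])^2 + (cgrid - pos[2])^2) / (2 * ev$radius^2))
        }
        data[ci, fi, , ] <- apply_noise(clean, config)
      }
      ok <- !is.na(traj[, 1])
      truth_punctum[[length(truth_punctum) + 1L]] <- list(
        mode = ev$mode, start_time = ev$time,
        trajectory = data.frame(time_s = times[ok], row = traj[ok, 1],
                                col = traj[ok, 2]),
        speed = config$speed, direction = dir)
    }
  })

  for (ev in frap_events) {
    truth_frap[[length(truth_frap) + 1L]] <- list(
      channel = ev$channel, bleach_time = ev$time, box = ev$box,
      bleach_depth = ev$bleach_depth, mobile_fraction = ev$mobile_fraction,
      rate_k = ev$rate_k)
  }

  out_labels <- c(labels,
                  if (length(pc_events)) paste0("converted",
                    if (length(pc_events) > 1) seq_along(pc_events) else ""))
  stack <- movie_stack(data, out_labels, config$pixel_size, config$frame_interval)
  truth <- sim_ground_truth(config, punctum = truth_punctum, frap = truth_frap)
  list(stack = stack, truth = truth)
}

channel_index_label <- function(labels, channel) {
  if (is.numeric(channel)) return(as.integer(channel))
  i <- match(channel, labels)
  if (is.na(i)) stopf("unknown event channel '%s'", channel)
  i
}

apply_noise <- function(clean, config) {
  out <- clean
  if (config$shot_noise) {
    out[] <- stats::rpois(length(out), lambda = pmax(out, 0))
  }
  if (config$noise_sigma > 0) {
    out <- out + stats::rnorm(length(out), 0, config$noise_sigma)
  }
  out
}

sim_ground_truth <- function(config, punctum = list(), frap = list()) {
  chans <- lapply(config$channels, function(ch) {
    list(label = ch$label, baseline = ch$baseline, amplitude = ch$amplitude,
         true_lag = ch$phase_offset, rise_fraction = ch$rise_fraction,
         anti_phase = ch$anti_phase)
  })
  structure(
    list(grid_shape = config$grid_shape, pixel_size = config$pixel_size,
         frame_interval = config$frame_interval, n_frames = config$n_frames,
         true_period = config$period, true_speed = config$speed,
         source = config$source, direction = config$direction,
         noise_sigma = config$noise_sigma, shot_noise = config$shot_noise,
         seed = config$seed, channels = chans, punctum = punctum, frap = frap),
    class = "sim_ground_truth")
}

#' Simulate ROI traces directly (fast path)
#'
#' Evaluates the channel model averaged over a single ROI without rendering
#' full frames. With `noise_sigma = 0` the result is identical to
#' [extract_roi_trace()] applied to the movie from [simulate_wave_movie()]
#' at the same ROI; with noise the two differ only in noise realisation.
#'
#' @param config a [sim_config()].
#' @param roi a [roi()]; default 20x20 px at the grid centre.
#' @return named list of [roi_trace()] objects, one per channel.
#' @export
simulate_traces <- function(config, roi = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(roi)) {
    roi <- roi(max(0L, config$grid_shape[1] %/% 2L - 10L),
               max(0L, config$grid_shape[2] %/% 2L - 10L),
               min(20L, config$grid_shape[1]), min(20L, config$grid_shape[2]))
  }
  roi_check_bounds(roi, config$grid_shape[1], config$grid_shape[2])
  d_full <- distance_map(config)
  d <- d_full[(roi$row0 + 1):(roi$row0 + roi$height),
              (roi$col0 + 1):(roi$col0 + roi$width)]
  d <- as.numeric(d)
  npix <- length(d)
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  out <- list()
  with_seed(config$seed, {
    for (ch in config$channels) {
      # outer(): npix x nframes matrix of phases in cycles
      u <- outer(-d / (config$speed * config$period),
                 (times - ch$phase_offset) / config$period, `+`)
      w <- wave_pulse(u, ch$rise_fraction)
      if (ch$anti_phase) w <- 1 - w
      clean <- ch$baseline + ch$amplitude * w
      if (config$shot_noise)
        clean[] <- stats::rpois(length(clean), pmax(clean, 0))
      if (config$noise_sigma > 0)
        clean <- clean + stats::rnorm(length(clean), 0, config$noise_sigma)
      out[[ch$label]] <- roi_trace(times, colMeans(matrix(clean, npix)),
                                   channel_label = ch$label, roi = roi)
    }
  })
  out
}

#' Simulate a persistent-random-walk cell track
#'
#' Steps have exactly length `step_speed * interval / 60` um; the heading
#' performs a wrapped-normal random walk with standard deviation
#' `(1 - persistence) * pi` per step, so `persistence = 1` gives a straight
#' line and `persistence = 0` nearly uncorrelated headings.
#'
#' @param n_steps number of steps (track has `n_steps + 1` points).
#' @param step_speed speed in um/min.
#' @param interval time between samples in seconds.
#' @param persistence directional persistence in [0, 1].
#' @param seed RNG seed.
#' @return A [track()].
#' @export
simulate_track <- function(n_steps, step_speed, interval = 30,
                           persistence = 0.5, seed = 1L) {
  if (!is_count(n_steps) || n_steps < 2) stopf("n_steps must be >= 2")
  if (step_speed < 0) stopf("step_speed must be >= 0")
  if (persistence < 0 || persistence > 1) stopf("persistence must be in [0, 1]")
  L <- step_speed * interval / 60
  with_seed(seed, {
    theta <- numeric(n_steps)
    theta[1] <- stats::runif(1, 0, 2 * pi)
    if (n_steps > 1) {
      dtheta <- stats::rnorm(n_steps - 1, 0, (1 - persistence) * pi)
      theta[-1] <- theta[1] + cumsum(dtheta)
    }
    x <- c(0, cumsum(L * cos(theta)))
    y <- c(0, cumsum(L * sin(theta)))
    track((0:n_steps) * interval, x, y)
  })
}

#' Simulate a FRAP recovery trace
#'
#' Baseline intensity up to `bleach_time`, then
#' `baseline * ((1 - depth) + depth * M * (1 - exp(-k (t - t_b))))` plus
#' Gaussian noise: single-exponential recovery of a bleached population with
#' mobile fraction `M` and rate `k`.
#'
#' @param mobile_fraction true mobile fraction M in [0, 1].
#' @param rate_k true recovery rate (1/s).
#' @param bleach_time bleach time in seconds.
#' @param duration total trace duration in seconds.
#' @param frame_interval sampling interval in seconds.
#' @param baseline pre-bleach intensity.
#' @param bleach_depth fraction of intensity removed at the bleach.
#' @param noise_sd Gaussian noise SD (same units as `baseline`).
#' @param seed RNG seed.
#' @return A [roi_trace()] with the true parameters attached as attribute
#'   `"truth"`.
#' @export
simulate_frap_trace <- function(mobile_fraction = 0.8, rate_k = 0.1,
                                bleach_time = 20, duration = 120,
                                frame_interval = 0.2, baseline = 1,
                                bleach_depth = 1, noise_sd = 0.01, seed = 1L) {
  times <- seq(0, duration, by = frame_interval)
  clean <- ifelse(times < bleach_time, baseline,
                  baseline * ((1 - bleach_depth) + bleach_depth *
                                mobile_fraction *
                                (1 - exp(-rate_k * (times - bleach_time)))))
  values <- with_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sd))
  tr <- roi_trace(times, values, channel_label = "frap")
  attr(tr, "truth") <- list(mobile_fraction = mobile_fraction, rate_k = rate_k,
                            bleach_time = bleach_time,
                            bleach_depth = bleach_depth)
  tr
}
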