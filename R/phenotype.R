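# Non-wave quantifications: cell-track velocimetry, photoconverted-punctum
# displacement classification, FRAP recovery fitting.

#' Mean cell velocity from a track
#'
#' Primary statistic: the mean over steps of (Euclidean step length / step
#' duration), in um/min. The net velocity (net displacement / total time) is
#' attached as attribute `"net_velocity"` for comparison; the two coincide
#' for straight-line motion.
#'
#' @param trk a [track()].
#' @return mean step speed in um/min.
#' @export
track_velocity <- function(trk) {
  stopifnot(inherits(trk, "track"))
  if (nrow(trk) < 2) stopf("track needs >= 2 samples")
  dtm <- diff(trk$time_s)
  if (any(dtm == 0)) stopf("duplicate timestamps in track")
  step <- sqrt(diff(trk$x_um)^2 + diff(trk$y_um)^2)
  v <- mean(step / dtm) * 60
  net <- sqrt((trk$x_um[nrow(trk)] - trk$x_um[1])^2 +
                (trk$y_um[nrow(trk)] - trk$y_um[1])^2) /
    (trk$time_s[nrow(trk)] - trk$time_s[1]) * 60
  attr(v, "net_velocity") <- net
  v
}

#' Track a bright punctum by windowed intensity centroid
#'
#' Follows a single bright spot frame by frame: within a square window of
#' radius `radius` pixels centred on the previous position, the local
#' median is subtracted (clamped at zero) and the intensity-weighted
#' centroid taken as the new position. Returns positions in physical units.
#'
#' @param stack a [movie_stack()].
#' @param channel channel label or index.
#' @param start (row, col) starting position in pixels (0-based).
#' @param start_time first frame time to track from (s).
#' @param radius tracking window radius in pixels.
#' @return A [track()] with attribute `"pixels"` (data.frame of row/col
#'   positions per frame).
#' @export
track_punctum <- function(stack, channel, start, start_time = 0, radius = 4L) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  ci <- channel_index(stack, channel)
  dt <- stack$frame_interval
  f0 <- as.integer(round(start_time / dt)) + 1L
  if (f0 < 1L || f0 > d[2]) stopf("start_time outside the movie span")
  pos <- as.numeric(start)
  times <- numeric(0); rs <- numeric(0); cs <- numeric(0)
  for (fi in f0:d[2]) {
    r0 <- max(0L, as.integer(round(pos[1])) - radius)
    r1 <- min(d[3] - 1L, as.integer(round(pos[1])) + radius)
    c0 <- max(0L, as.integer(round(pos[2])) - radius)
    c1 <- min(d[4] - 1L, as.integer(round(pos[2])) + radius)
    win <- stack$data[ci, fi, (r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)]
    w <- pmax(win - stats::median(win), 0)
    if (sum(w) > 0) {
      rg <- r0:r1; cg <- c0:c1
      pos <- c(sum(rowSums(w) * rg) / sum(w), sum(colSums(w) * cg) / sum(w))
    }
    times <- c(times, (fi - 1L) * dt); rs <- c(rs, pos[1]); cs <- c(cs, pos[2])
  }
  trk <- track(times, cs * stack$pixel_size, rs * stack$pixel_size)
  attr(trk, "pixels") <- data.frame(time_s = times, row = rs, col = cs)
  trk
}

#' Classify a photoconverted punctum as stationary or advected
#'
#' Distinguishes wave propagation by de novo nucleation (converted material
#' stays put while the wave moves on) from bulk advection (material rides
#' the wave). The punctum is `"stationary"` when its total displacement is
#' below `max(2 pixels, 0.1 * speed * duration)`, `"advected"` when its
#' displacement projected on the wave direction exceeds
#' `0.5 * speed * duration`, and `"ambiguous"` otherwise.
#'
#' @param trk punctum [track()] (um coordinates; x = col, y = row axis).
#' @param wave_speed wave propagation speed (um/s).
#' @param wave_direction propagation direction in radians (0 = +x/+col), or
#'   a (row, col) unit vector.
#' @param pixel_size um per pixel (for the 2-pixel floor).
#' @param duration observation span in seconds; default the track span.
#' @return An object of class `punctum_verdict`: list with
#'   `total_displacement_um`, `path_length_um`, `expected_advection_um`,
#'   `along_wave_um`, `classification`.
#' @export
punctum_displacement_test <- function(trk, wave_speed, wave_direction,
                                      pixel_size, duration = NULL) {
  stopifnot(inherits(trk, "track"))
  if (nrow(trk) < 3) stopf("punctum track must span >= 3 frames")
  duration <- duration %||% (trk$time_s[nrow(trk)] - trk$time_s[1])
  dx <- trk$x_um[nrow(trk)] - trk$x_um[1]
  dy <- trk$y_um[nrow(trk)] - trk$y_um[1]
  disp <- sqrt(dx^2 + dy^2)
  path <- sum(sqrt(diff(trk$x_um)^2 + diff(trk$y_um)^2))
  if (length(wave_direction) == 2) {
    # (row, col) vector: col maps to x, row to y
    u <- wave_direction / sqrt(sum(wave_direction^2))
    along <- dx * u[2] + dy * u[1]
  } else {
    along <- dx * cos(wave_direction) + dy * sin(wave_direction)
  }
  expected <- wave_speed * duration
  cls <- if (disp < max(2 * pixel_size, 0.1 * expected)) "stationary"
         else if (along > 0.5 * expected) "advected"
         else "ambiguous"
  structure(list(total_displacement_um = disp, path_length_um = path,
                 expected_advection_um = expected, along_wave_um = along,
                 classification = cls),
            class = "punctum_verdict")
}

#' @export
print.punctum_verdict <- function(x, ...) {
  cat(sprintf("punctum_verdict: %s (displacement %.2f um, expected advection %.2f um)\n",
              x$classification, x$total_displacement_um, x$expected_advection_um))
  invisible(x)
}

#' Fit a FRAP recovery curve
#'
#' Normalizes the trace so the pre-bleach mean maps to 1 and the first
#' post-bleach frame to 0, then fits the single-exponential recovery
#' `I(t) = M (1 - exp(-k (t - t_b)))` by nonlinear least squares. `M` is the
#' mobile fraction of the bleached population and `k` the exchange rate;
#' `half_time = ln(2)/k`. No reference-region photofading correction is
#' applied.
#'
#' @param trace a [roi_trace()] over the bleached region.
#' @param bleach_time bleach time in seconds; >= 5 pre-bleach and >= 20
#'   post-bleach frames are required.
#' @return An object of class `frap_result`: list with `curve` (data.frame
#'   `time_s`, `normalized`), `mobile_fraction`, `rate_k`, `half_time`,
#'   `residual_rms`, `flag` (`NULL`, `"no_fit"` or `"rate_at_bound"`).
#' @export
frap_recovery <- function(trace, bleach_time) {
  stopifnot(inherits(trace, "roi_trace"))
  t <- trace$times; v <- trace$values
  pre <- which(t < bleach_time)
  post <- which(t >= bleach_time)
  if (length(pre) < 5) stopf("need >= 5 pre-bleach frames, got %d", length(pre))
  if (length(post) < 20) stopf("need >= 20 post-bleach frames, got %d", length(post))
  pre_mean <- mean(v[pre])
  i0 <- post[1]
  if ((pre_mean - v[i0]) / pre_mean < 0.10)
    stopf("no bleach detected: intensity dip at t = %.3g s is below 10%%", bleach_time)
  norm <- (v[post] - v[i0]) / (pre_mean - v[i0])
  tp <- t[post] - t[i0]
  curve <- data.frame(time_s = t[post], normalized = norm)
  plateau <- mean(norm[tp >= stats::quantile(tp, 0.8)])
  M0 <- min(max(plateau, 0.05), 1)
  # crude initial rate from the time to reach half the plateau
  t_half <- tp[which(norm >= M0 / 2)[1]]
  k0 <- if (!is.na(t_half) && t_half > 0) log(2) / t_half else 1 / max(tp)
  dtf <- tp[2] - tp[1]
  k_hi <- 5 / dtf   # recovery faster than a few frames is unresolvable
  fit <- tryCatch(
    minpack.lm::nlsLM(norm ~ M * (1 - exp(-k * tp)),
                      start = list(M = M0, k = k0),
                      lower = c(0, 1e-6), upper = c(1.5, k_hi),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # exponential fit can fail when there is essentially no recovery; the
    # plateau estimate still reports the mobile fraction
    return(structure(list(curve = curve,
                          mobile_fraction = min(max(plateau, 0), 1),
                          rate_k = NA_real_, half_time = NA_real_,
                          residual_rms = NA_real_, flag = "no_fit"),
                     class = "frap_result"))
  }
  co <- stats::coef(fit)
  flag <- if (co[["k"]] >= 0.99 * k_hi) "rate_at_bound" else NULL
  structure(list(curve = curve,
                 mobile_fraction = unname(co[["M"]]),
                 rate_k = unname(co[["k"]]),
                 half_time = log(2) / unname(co[["k"]]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 flag = flag),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("frap_result: mobile fraction %.3f, k = %.4g /s (t1/2 = %.3g s)%s\n",
              x$mobile_fraction, x$rate_k, x$half_time,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}
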