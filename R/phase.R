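# Pairwise temporal relationships: cross-correlation lags with sub-frame
# refinement, cycle detection, peak-aligned average profiles, waveform
# asymmetry and anti-phase scoring.
#
# Sign convention throughout: negative lag = probe precedes (peaks earlier
# than) the reference; probe(t) ~ reference(t - lag).

lag_estimate <- function(lag, peak_correlation, search_halfwidth, method,
                         status = "ok") {
  structure(list(lag = lag, peak_correlation = peak_correlation,
                 search_halfwidth = search_halfwidth, method = method,
                 status = status),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("lag_estimate (%s): %+.3f s (r = %.3f, search +/-%.3g s)%s\n",
              x$method, x$lag, x$peak_correlation, x$search_halfwidth,
              if (x$status == "ok") "" else paste0(" [", x$status, "]")))
  invisible(x)
}

## Overlap-restricted Pearson correlation of probe shifted by `shift` frames
## against reference (positive shift: probe delayed).
shifted_correlation <- function(probe, reference, shift) {
  n <- length(probe)
  if (shift >= 0) {
    a <- probe[(shift + 1):n]; b <- reference[1:(n - shift)]
  } else {
    a <- probe[1:(n + shift)]; b <- reference[(1 - shift):n]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Cross-correlation lag between two traces
#'
#' Scans integer frame shifts within `+/- search_halfwidth`, computing the
#' overlap-restricted (no zero padding) Pearson correlation at each shift,
#' and refines the maximum below frame resolution by parabolic interpolation
#' of the correlation at the discrete peak and its neighbours. Negative lag
#' means the probe precedes the reference.
#'
#' @param probe,reference detrended [roi_trace()]s with equal sampling.
#' @param search_halfwidth maximal |lag| in seconds; default 0.6 x the
#'   reference's dominant period (from its periodogram), guarding against
#'   period-aliased picks.
#' @param period optional known dominant period (s); used for the default
#'   halfwidth and the short-overlap warning flag.
#' @return A `lag_estimate` (method `"ccf"`); `status` is `"short_overlap"`
#'   when fewer than 3 periods overlap.
#' @export
cross_correlation <- function(probe, reference, search_halfwidth = NULL,
                              period = NULL) {
  stopifnot(inherits(probe, "roi_trace"), inherits(reference, "roi_trace"))
  dt_p <- trace_dt(probe); dt_r <- trace_dt(reference)
  if (abs(dt_p - dt_r) > 1e-9 * dt_r) stopf("traces have different sampling intervals")
  if (length(probe) != length(reference))
    stopf("traces have different lengths (%d vs %d)", length(probe), length(reference))
  if (stats::sd(probe$values) == 0 || stats::sd(reference$values) == 0)
    stopf("constant trace: cross-correlation undefined")
  dt <- dt_r
  n <- length(reference)
  if (is.null(search_halfwidth)) {
    if (is.null(period) && n >= 32) {
      sp <- periodogram(reference)
      f <- sp$frequencies
      in_band <- f > 0 & 1 / f >= sp$band[1] & 1 / f <= sp$band[2]
      period <- 1 / f[which(in_band)[which.max(sp$power[in_band])]]
    }
    search_halfwidth <- if (!is.null(period)) 0.6 * period else n * dt / 4
  }
  max_shift <- min(n - 3L, floor(search_halfwidth / dt))
  if (max_shift < 1) stopf("search_halfwidth below one frame")
  shifts <- (-max_shift):max_shift
  r <- vapply(shifts, function(s) shifted_correlation(probe$values,
                                                      reference$values, s),
              numeric(1))
  if (all(is.na(r))) stopf("correlation undefined at every shift")
  i <- which.max(r)
  lag <- parabolic_refine(shifts * dt, r, i)
  status <- "ok"
  if (!is.null(period) && n * dt < 3 * period) status <- "short_overlap"
  lag_estimate(lag, r[i], max_shift * dt, "ccf", status)
}

#' Detect oscillation cycle peaks
#'
#' Local maxima of a detrended trace with topographic prominence at least
#' `prominence_min` and separation at least half the dominant period. Used
#' to anchor peak-aligned average profiles.
#'
#' When `refine = TRUE` (default) each discrete peak time is refined below
#' frame resolution by a least-squares quadratic fit to the trace within
#' 1/8 period of the peak; this matters because smooth, flat-topped waves
#' let noise move the discrete argmax by several frames.
#'
#' @param trace detrended [roi_trace()].
#' @param call the trace's `wave_call` (must be `is_wave`).
#' @param prominence_min minimal prominence; default half the 5th-95th
#'   percentile span of the trace.
#' @param refine refine peak times below frame resolution.
#' @return numeric vector of peak times (s).
#' @export
detect_cycles <- function(trace, call, prominence_min = NULL, refine = TRUE) {
  stopifnot(inherits(trace, "roi_trace"), inherits(call, "wave_call"))
  if (!call$is_wave) stopf("trace was not called as a wave; no cycles to detect")
  dt <- trace_dt(trace)
  v <- trace$values
  if (call$polarity == "negative") v <- -v   # align pulses upward
  prominence_min <- prominence_min %||%
    (0.5 * diff(stats::quantile(v, c(0.05, 0.95), names = FALSE)))
  sep <- max(1L, floor(0.5 * call$dominant_period / dt))
  idx <- find_peaks(v, prominence_min = prominence_min, min_separation = sep)
  pk <- trace$times[idx]
  if (refine && length(pk)) {
    hw <- max(2 * dt, call$dominant_period / 8)
    pk <- vapply(pk, function(p) {
      # iterate the local quadratic fit, re-centring the window on the
      # current vertex: a discrete argmax displaced along a flat peak would
      # otherwise anchor the fit on one flank
      for (it in 1:3) {
        j <- which(abs(trace$times - p) <= hw)
        if (length(j) < 5) break
        vtx <- quad_vertex(trace$times[j], v[j])
        if (is.na(vtx) || abs(vtx - p) > hw) break
        if (abs(vtx - p) < dt / 10) { p <- vtx; break }
        p <- vtx
      }
      p
    }, numeric(1))
  }
  pk
}

#' Peak-aligned average cycle profile
#'
#' Averages the probe trace over windows of `+/- window/2` centred on each
#' reference peak; incomplete edge windows are dropped. Peak times may be
#' fractional (sub-frame): windows are sampled on the exact peak-relative
#' grid by linear interpolation, so refined peak times from
#' [detect_cycles()] align cycles without frame quantization. The mean and
#' standard deviation across cycles describe the probe's waveform relative
#' to the reference's phase.
#'
#' @param probe [roi_trace()] (detrended recommended).
#' @param ref_peaks reference peak times (s), e.g. from [detect_cycles()].
#' @param window full window width in seconds (at most one period for
#'   non-overlapping cycles).
#' @return An object of class `average_profile`: list with `rel_times` (s,
#'   zero at the reference peak), `mean`, `sd`, `n_cycles`.
#' @export
average_profile <- function(probe, ref_peaks, window) {
  stopifnot(inherits(probe, "roi_trace"))
  dt <- trace_dt(probe)
  h <- floor((window / 2) / dt)
  if (h < 1) stopf("window shorter than one frame")
  rel <- ((-h):h) * dt
  n <- length(probe)
  rows <- list()
  for (pk in ref_peaks) {
    tt <- pk + rel
    if (tt[1] >= probe$times[1] - 1e-9 && tt[length(tt)] <= probe$times[n] + 1e-9)
      rows[[length(rows) + 1L]] <-
        stats::approx(probe$times, probe$values, tt, rule = 2)$y
  }
  if (length(rows) < 3)
    stopf("only %d complete cycle window(s); at least 3 are required", length(rows))
  m <- do.call(rbind, rows)
  structure(list(rel_times = rel, mean = colMeans(m),
                 sd = apply(m, 2, stats::sd), n_cycles = nrow(m)),
            class = "average_profile")
}

#' @export
print.average_profile <- function(x, ...) {
  cat(sprintf("average_profile: %d cycles, window %.3g..%.3g s\n",
              x$n_cycles, min(x$rel_times), max(x$rel_times)))
  invisible(x)
}

#' @export
plot.average_profile <- function(x, ...) {
  graphics::plot(x$rel_times, x$mean, type = "n",
                 ylim = range(c(x$mean - x$sd, x$mean + x$sd)),
                 xlab = "time from reference peak (s)", ylab = "intensity", ...)
  graphics::polygon(c(x$rel_times, rev(x$rel_times)),
                    c(x$mean - x$sd, rev(x$mean + x$sd)),
                    col = grDevices::adjustcolor("gray", 0.5), border = NA)
  graphics::lines(x$rel_times, x$mean, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Phase lag from an average profile
#'
#' The lag is the relative time of the profile mean's maximum, refined by
#' parabolic interpolation. A maximum on the window edge (or a flat profile)
#' is reported as `"unresolved"` rather than a number.
#'
#' @param profile an `average_profile`.
#' @return A `lag_estimate` (method `"profile"`).
#' @export
profile_lag <- function(profile) {
  stopifnot(inherits(profile, "average_profile"))
  m <- profile$mean
  hw <- max(abs(profile$rel_times))
  if (diff(range(m)) == 0)
    return(lag_estimate(NA_real_, NA_real_, hw, "profile", "unresolved"))
  i <- which.max(m)
  if (i == 1L || i == length(m))
    return(lag_estimate(NA_real_, NA_real_, hw, "profile", "unresolved"))
  # local least-squares quadratic around the maximum: averages noise on the
  # broad peaks left by ROI smoothing, where a 3-point parabola would jitter
  k <- max(2L, round(0.1 * length(m)))
  j <- max(1L, i - k):min(length(m), i + k)
  v <- quad_vertex(profile$rel_times[j], m[j])
  if (is.na(v) || v < profile$rel_times[j[1]] || v > profile$rel_times[j[length(j)]])
    v <- parabolic_refine(profile$rel_times, m, i)
  lag_estimate(v, NA_real_, hw, "profile")
}

#' Waveform asymmetry index
#'
#' Ratio of rise duration (preceding trough to peak) to fall duration (peak
#' to following trough) of the average cycle. The profile window is treated
#' as one full period (cyclically), so a sawtooth that rises over 75% of its
#' period scores 3. Values above 1 indicate the gentle-rise / sharp-fall
#' waveform characteristic of slow assembly and fast disassembly.
#'
#' @param profile an `average_profile` spanning approximately one period.
#' @return list with `index` (rise/fall ratio, `NA` when unresolved),
#'   `rise_s`, `fall_s`, `status`.
#' @export
asymmetry_index <- function(profile) {
  stopifnot(inherits(profile, "average_profile"))
  m <- profile$mean
  n <- length(m)
  dt <- profile$rel_times[2] - profile$rel_times[1]
  if (diff(range(m)) == 0)
    return(list(index = NA_real_, rise_s = NA_real_, fall_s = NA_real_,
                status = "unresolved"))
  ip <- which.max(m)
  it <- which.min(m)
  period <- n * dt
  rise <- ((ip - it) %% n) * dt
  fall <- period - rise
  if (rise <= 0 || fall <= 0 || rise < dt / 2 || fall < dt / 2)
    return(list(index = NA_real_, rise_s = rise, fall_s = fall,
                status = "unresolved"))
  list(index = rise / fall, rise_s = rise, fall_s = fall, status = "ok")
}

#' Anti-phase score between two oscillating traces
#'
#' Reports the Pearson correlation at zero lag and the cross-correlation
#' |lag| as a fraction of the dominant period (folded into 0-0.5). The pair
#' is flagged anti-phase when the zero-lag correlation is below
#' `-anti_thresh` and the lag fraction exceeds 0.35 — the signature of, e.g.,
#' microtubule density dipping half a period out of step with the actin wave.
#'
#' @param probe,reference raw or detrended [roi_trace()]s; both must be
#'   wave-positive with dominant periods agreeing within 20%.
#' @param anti_thresh zero-lag correlation magnitude required.
#' @param window detrending window (s) applied when traces are not yet
#'   detrended.
#' @return list with `zero_lag_correlation`, `lag_fraction`, `lag_s`,
#'   `period_s`, `anti_phase` (logical).
#' @export
anti_phase_score <- function(probe, reference, anti_thresh = 0.5, window = 80) {
  prep <- function(tr) {
    if (isTRUE(attr(tr, "detrended"))) {
      sp <- periodogram(tr)
      list(trace = tr, call = classify_wave(sp, tr))
    } else {
      call <- call_wave(tr, window)
      list(trace = attr(call, "detrended_trace"), call = call)
    }
  }
  p <- prep(probe); r <- prep(reference)
  if (!p$call$is_wave || !r$call$is_wave)
    stopf("both traces must be called as waves for anti-phase scoring")
  Tp <- p$call$dominant_period; Tr <- r$call$dominant_period
  if (abs(Tp - Tr) > 0.2 * Tr)
    stopf("dominant periods differ by more than 20%% (%.3g vs %.3g s)", Tp, Tr)
  period <- (Tp + Tr) / 2
  r0 <- stats::cor(p$trace$values, r$trace$values)
  le <- cross_correlation(p$trace, r$trace, search_halfwidth = 0.6 * period,
                          period = period)
  frac <- abs(le$lag) / period
  frac <- min(frac, 1 - frac)
  list(zero_lag_correlation = r0, lag_fraction = frac, lag_s = le$lag,
       period_s = period, anti_phase = r0 < -anti_thresh && frac > 0.35)
}
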