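# Spatial reductions: ROI traces, kymographs (reslice along a line),
# time projections, and kymograph-based wave-speed estimation.

#' Extract a mean-intensity ROI trace
#'
#' The value at each frame is the arithmetic mean of the pixel intensities
#' inside the ROI; times follow the stack's frame interval with the first
#' frame at t = 0.
#'
#' @param stack a [movie_stack()].
#' @param roi a [roi()], fully inside the image.
#' @param channel channel label or index.
#' @return A [roi_trace()].
#' @export
extract_roi_trace <- function(stack, roi, channel) {
  stopifnot(inherits(stack, "movie_stack"), inherits(roi, "roi"))
  d <- dim(stack$data)
  roi_check_bounds(roi, d[3], d[4])
  ci <- channel_index(stack, channel)
  rows <- (roi$row0 + 1):(roi$row0 + roi$height)
  cols <- (roi$col0 + 1):(roi$col0 + roi$width)
  vals <- vapply(seq_len(d[2]),
                 function(fi) mean(stack$data[ci, fi, rows, cols]),
                 numeric(1))
  roi_trace((seq_len(d[2]) - 1) * stack$frame_interval, vals,
            channel_label = stack$channel_labels[ci], roi = roi)
}

#' Build a kymograph by reslicing along a line
#'
#' Samples the movie along the line at unit-pixel steps with bilinear
#' interpolation; when `averaging_width > 1`, symmetric parallel offsets
#' perpendicular to the line are averaged. Rows are frames (time), columns
#' positions along the line.
#'
#' @param stack a [movie_stack()].
#' @param line a [line_spec()].
#' @param channel channel label or index.
#' @return An object of class `kymograph`: list with `data`
#'   (time x position), `position_step` (um), `frame_interval` (s), `line`.
#' @export
make_kymograph <- function(stack, line, channel) {
  stopifnot(inherits(stack, "movie_stack"), inherits(line, "line_spec"))
  d <- dim(stack$data)
  ci <- channel_index(stack, channel)
  delta <- line$to - line$from
  len <- sqrt(sum(delta^2))
  u <- delta / len                      # along-line unit vector (row, col)
  perp <- c(-u[2], u[1])
  n_pos <- floor(len) + 1L
  s <- 0:(n_pos - 1L)
  offs <- seq(-(line$averaging_width - 1L) / 2, (line$averaging_width - 1L) / 2)
  rr <- outer(line$from[1] + s * u[1], offs * perp[1], `+`)
  cc <- outer(line$from[2] + s * u[2], offs * perp[2], `+`)
  if (any(rr < 0 | rr > d[3] - 1 | cc < 0 | cc > d[4] - 1))
    stopf("line (with averaging width %d) leaves the image bounds",
          line$averaging_width)
  km <- matrix(0, d[2], n_pos)
  for (fi in seq_len(d[2])) {
    img <- stack$data[ci, fi, , ]
    v <- bilinear_sample(img, as.numeric(rr), as.numeric(cc))
    km[fi, ] <- rowMeans(matrix(v, n_pos))
  }
  structure(list(data = km, position_step = stack$pixel_size,
                 frame_interval = stack$frame_interval, line = line),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions (%.4g s, %.4g um steps)\n",
              nrow(x$data), ncol(x$data), x$frame_interval, x$position_step))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = (seq_len(ncol(x$data)) - 1) * x$position_step,
                  y = (seq_len(nrow(x$data)) - 1) * x$frame_interval,
                  z = t(x$data), xlab = "position (um)", ylab = "time (s)",
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

#' Three-frame RGB time projection
#'
#' Encodes wave motion as colour: the frames at `t0`, `t0 + interval` and
#' `t0 + 2 * interval` become the red, green and blue planes, each
#' independently contrast-stretched between its 1st and 99th intensity
#' percentiles. A static scene yields a gray composite; a travelling wave
#' yields spatially shifted coloured bands.
#'
#' @param stack a [movie_stack()].
#' @param channel channel label or index.
#' @param t0 time of the red frame (s).
#' @param interval spacing between projected frames (s); must align to the
#'   frame grid.
#' @return rows x cols x 3 array (R, G, B in `[0, 1]`), class `rgb_composite`.
#' @export
time_projection <- function(stack, channel, t0, interval) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  ci <- channel_index(stack, channel)
  dt <- stack$frame_interval
  tt <- t0 + (0:2) * interval
  fi <- tt / dt + 1
  if (any(abs(fi - round(fi)) > 1e-6))
    stopf("t0/interval do not align to the %.4g s frame grid", dt)
  fi <- as.integer(round(fi))
  if (any(fi < 1 | fi > d[2]))
    stopf("projection frames at t = %s s fall outside the movie span",
          paste(tt[fi < 1 | fi > d[2]], collapse = ", "))
  out <- array(0, dim = c(d[3], d[4], 3))
  for (k in 1:3) {
    img <- stack$data[ci, fi[k], , ]
    q <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
    if (q[2] > q[1]) img <- (img - q[1]) / (q[2] - q[1]) else img <- img * 0
    out[, , k] <- pmin(pmax(img, 0), 1)
  }
  structure(out, class = c("rgb_composite", "array"),
            times = tt, channel = stack$channel_labels[ci])
}

#' Estimate wave speed from a kymograph
#'
#' A travelling wave appears as oriented stripes of slope 1/v in the
#' (position, time) plane. The slope is found by shear projection: for each
#' candidate slope, the kymograph is averaged along lines of that slope and
#' the variance of the projected profile is computed; the dominant stripe
#' orientation maximizes this variance. 180 orientations are scanned and the
#' maximum is refined by a parabolic fit. A flat or incoherent kymograph
#' (low peak sharpness) or a best slope of zero (static pattern) yields an
#' `"undetermined"` result rather than a number.
#'
#' @param kymo a `kymograph` from [make_kymograph()].
#' @param n_orientations number of candidate stripe orientations.
#' @param min_sharpness minimum (peak - median)/median contrast of the
#'   orientation-variance curve for a determinate answer.
#' @return list with `status` (`"ok"` or `"undetermined"`), `speed` (um/s,
#'   `NA` when undetermined), `confidence` (peak sharpness) and
#'   `slope_px_per_frame`.
#' @export
estimate_wave_speed <- function(kymo, n_orientations = 180L,
                                min_sharpness = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$data
  K <- sweep(K, 1, rowMeans(K))  # remove per-frame offsets
  nt <- nrow(K); np <- ncol(K)
  thetas <- seq(-pi / 2, pi / 2, length.out = n_orientations + 2L)
  thetas <- thetas[-c(1L, n_orientations + 2L)]
  tgrid <- seq_len(nt) - 1
  vars <- vapply(thetas, function(th) {
    c_slope <- tan(th)                      # px per frame
    proj <- numeric(np); cnt <- numeric(np)
    # average K[t, x0 + c*t] over t for each launch position x0
    for (ti in seq_len(nt)) {
      shift <- c_slope * tgrid[ti]
      x <- seq_len(np) - 1 + shift          # source position for each x0
      xi <- floor(x); fr <- x - xi
      ok <- xi >= 0 & xi <= np - 2
      idx <- which(ok)
      if (!length(idx)) next
      v <- K[ti, xi[idx] + 1] * (1 - fr[idx]) + K[ti, xi[idx] + 2] * fr[idx]
      proj[idx] <- proj[idx] + v
      cnt[idx] <- cnt[idx] + 1
    }
    use <- cnt >= max(8, nt / 4)
    if (sum(use) < 4) return(NA_real_)
    # normalize by the noise-variance scaling of unequal averaging counts,
    # so incoherent noise gives a flat orientation response
    stats::var(proj[use] / cnt[use]) / mean(1 / cnt[use])
  }, numeric(1))
  if (all(is.na(vars)) || max(vars, na.rm = TRUE) == 0)
    return(list(status = "undetermined", speed = NA_real_, confidence = 0,
                slope_px_per_frame = NA_real_))
  i <- which.max(vars)
  med <- stats::median(vars, na.rm = TRUE)
  sharp <- if (med > 0) (vars[i] - med) / med else Inf
  # refine in slope space (tan is nonlinear in theta, so the vertex is
  # fitted on the three (slope, variance) points directly)
  slope <- tan(thetas[i]); th <- thetas[i]
  if (i > 1L && i < length(thetas) && !is.na(vars[i - 1]) && !is.na(vars[i + 1])) {
    cc <- tan(thetas[(i - 1):(i + 1)])
    v <- quad_vertex(cc, vars[(i - 1):(i + 1)])
    if (!is.na(v) && v >= cc[1] && v <= cc[3]) { slope <- v; th <- atan(v) }
  }
  dth <- thetas[2] - thetas[1]
  if (sharp < min_sharpness || abs(th) < dth)
    return(list(status = "undetermined", speed = NA_real_, confidence = sharp,
                slope_px_per_frame = slope))
  list(status = "ok",
       speed = abs(slope) * kymo$position_step / kymo$frame_interval,
       confidence = sharp, slope_px_per_frame = slope)
}
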