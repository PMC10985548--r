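#' Multi-channel movie stack
#'
#' Container for a calibrated multi-channel 2D time-lapse: a 4-D intensity
#' array indexed (channel, frame, row, col), with channel labels and physical
#' calibration. Frame `i` (1-based) is acquired at time `(i - 1) *
#' frame_interval` seconds.
#'
#' @param data 4-D numeric array with dimensions (channel, frame, row, col).
#' @param channel_labels character vector, one label per channel.
#' @param pixel_size pixel pitch in micrometres per pixel.
#' @param frame_interval time between frames in seconds.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, channel_labels, pixel_size, frame_interval) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("`data` must be a 4-D array (channel, frame, row, col)")
  if (dim(data)[1] != length(channel_labels))
    stopf("number of channels (%d) != number of labels (%d)",
          dim(data)[1], length(channel_labels))
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stopf("`pixel_size` must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stopf("`frame_interval` must be > 0")
  if (dim(data)[2] < 2L) stopf("a movie needs at least 2 frames")
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         pixel_size = pixel_size, frame_interval = frame_interval),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d channel(s) [%s], %d frames of %dx%d px\n",
              d[1], paste(x$channel_labels, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  pixel %.4g um, interval %.4g s (%.3g s total)\n",
              x$pixel_size, x$frame_interval, (d[2] - 1) * x$frame_interval))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    i <- as.integer(channel)
    if (i < 1L || i > length(stack$channel_labels)) stopf("channel index %d out of range", i)
    return(i)
  }
  i <- match(channel, stack$channel_labels)
  if (is.na(i))
    stopf("unknown channel '%s' (have: %s)", channel,
          paste(stack$channel_labels, collapse = ", "))
  i
}

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle: rows `row0 .. row0+height-1`, columns
#' `col0 .. col0+width-1`. The default 20x20 px matches common practice for
#' cortical-wave intensity traces.
#'
#' @param row0,col0 0-based top-left corner in pixels.
#' @param height,width extent in pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height = 20L, width = 20L) {
  for (v in list(row0, col0, height, width))
    if (!is_count(v) || v < 0) stopf("roi fields must be non-negative integers")
  if (height < 1 || width < 1) stopf("roi extent must be >= 1 px")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

roi_check_bounds <- function(r, nrow, ncol) {
  if (r$row0 + r$height > nrow || r$col0 + r$width > ncol)
    stopf("roi [%d:%d, %d:%d] exceeds image bounds %dx%d",
          r$row0, r$row0 + r$height, r$col0, r$col0 + r$width, nrow, ncol)
  invisible(TRUE)
}

#' Line specification for kymographs
#'
#' @param from,to numeric length-2 vectors, (row, col) endpoints in 0-based
#'   pixel coordinates.
#' @param averaging_width odd integer; number of parallel lines averaged
#'   perpendicular to the main line.
#' @return An object of class `line_spec`.
#' @export
line_spec <- function(from, to, averaging_width = 1L) {
  from <- as.numeric(from); to <- as.numeric(to)
  if (length(from) != 2L || length(to) != 2L) stopf("endpoints must be (row, col) pairs")
  if (all(from == to)) stopf("degenerate line: endpoints coincide")
  if (!is_count(averaging_width) || averaging_width < 1 || averaging_width %% 2 == 0)
    stopf("`averaging_width` must be a positive odd integer")
  structure(list(from = from, to = to, averaging_width = as.integer(averaging_width)),
            class = "line_spec")
}

#' Uniformly sampled intensity trace
#'
#' @param times sample times in seconds, uniformly spaced, starting anywhere.
#' @param values intensities (arbitrary units), same length as `times`.
#' @param channel_label channel name the trace came from.
#' @param roi optional [roi()] the trace was averaged over.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(times, values, channel_label = "trace", roi = NULL) {
  if (length(times) != length(values)) stopf("times and values differ in length")
  if (length(times) < 2L) stopf("a trace needs at least 2 samples")
  dt <- diff(times)
  if (any(dt <= 0)) stopf("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stopf("non-uniform sampling: frame intervals range %.6g..%.6g s", min(dt), max(dt))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 channel_label = channel_label, roi = roi),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("roi_trace '%s': %d samples @ %.4g s (%.4g..%.4g s)\n",
              x$channel_label, length(x$times), trace_dt(x),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.roi_trace <- function(x) length(x$values)

trace_dt <- function(trace) {
  n <- length(trace$times)
  (trace$times[n] - trace$times[1]) / (n - 1)
}

#' Cell track
#'
#' Positions of a tracked object over time, in physical units.
#'
#' @param times seconds, strictly increasing.
#' @param x,y coordinates in micrometres.
#' @return An object of class `track`: a data.frame with columns
#'   `time_s`, `x_um`, `y_um`.
#' @export
track <- function(times, x, y) {
  if (length(times) != length(x) || length(times) != length(y))
    stopf("times, x, y must have equal length")
  if (any(diff(times) <= 0)) stopf("track times must be strictly increasing")
  structure(data.frame(time_s = as.numeric(times), x_um = as.numeric(x),
                       y_um = as.numeric(y)),
            class = c("track", "data.frame"))
}
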