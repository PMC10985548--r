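# Stack / trace / track I/O.
#
# TIFF carries pixels only; all calibration (pixel size, frame interval,
# channel labels, axis order, intensity scaling) travels in a JSON sidecar
# written next to the TIFF. Readers reject rather than repair: a missing
# sidecar or a malformed time axis is an error, never a silent default.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a movie stack to TIFF + JSON sidecar
#'
#' Pages are written frame-major within channel (channel 1 frames, then
#' channel 2 frames, ...) or interleaved (frame 1 all channels, ...);
#' the order is recorded in the sidecar. Integer-valued data in
#' `[0, 2^bits - 1]` round-trips bit-exactly; other data is affinely
#' quantized to the available bit depth with offset/scale recorded in the
#' sidecar (relative error <= 2^-bits of the dynamic range).
#'
#' @param stack a [movie_stack()].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param interleave if `TRUE`, pages cycle through channels within each
#'   frame; otherwise channels are stored as consecutive blocks.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, interleave = FALSE, bits = 16L) {
  stopifnot(inherits(stack, "movie_stack"))
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  d <- dim(stack$data)
  maxval <- 2^bits - 1
  x <- stack$data
  integral <- all(x == round(x)) && min(x) >= 0 && max(x) <= maxval
  if (integral) {
    offset <- 0; scale <- maxval
  } else {
    offset <- min(x)
    rng <- max(x) - offset
    scale <- if (rng > 0) rng else 1
    x <- round((x - offset) / scale * maxval)
  }
  pages <- list()
  idx <- if (interleave) {
    expand.grid(ch = seq_len(d[1]), fr = seq_len(d[2]))[, c("ch", "fr")]
  } else {
    g <- expand.grid(fr = seq_len(d[2]), ch = seq_len(d[1]))
    data.frame(ch = g$ch, fr = g$fr)
  }
  for (i in seq_len(nrow(idx))) {
    pages[[i]] <- (if (integral) x[idx$ch[i], idx$fr[i], , ] else
      x[idx$ch[i], idx$fr[i], , ]) / maxval
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(format = "cortexwave-stack", version = 1L,
               n_channels = d[1], n_frames = d[2], rows = d[3], cols = d[4],
               channel_labels = stack$channel_labels,
               pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               interleaved = interleave, bits = bits,
               offset = offset, scale = scale, integral = integral)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie stack written by [write_stack()]
#'
#' @param path TIFF path; calibration is read from `<path>.json`.
#' @return A [movie_stack()].
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!file.exists(sc))
    stopf("missing calibration sidecar '%s': pixel_size_um and frame_interval_s are required", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("pixel_size_um", "frame_interval_s", "n_channels", "n_frames",
              "channel_labels", "interleaved", "offset", "scale", "bits"))
    if (is.null(meta[[f]])) stopf("sidecar is missing required field '%s'", f)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- meta$n_channels; nfr <- meta$n_frames
  if (length(pages) != nch * nfr)
    stopf("TIFF has %d pages, sidecar promises %d channels x %d frames",
          length(pages), nch, nfr)
  rows <- nrow(pages[[1]]); cols <- ncol(pages[[1]])
  maxval <- 2^meta$bits - 1
  data <- array(0, dim = c(nch, nfr, rows, cols))
  k <- 1L
  if (isTRUE(meta$interleaved)) {
    for (fr in seq_len(nfr)) for (ch in seq_len(nch)) {
      data[ch, fr, , ] <- pages[[k]]; k <- k + 1L
    }
  } else {
    for (ch in seq_len(nch)) for (fr in seq_len(nfr)) {
      data[ch, fr, , ] <- pages[[k]]; k <- k + 1L
    }
  }
  data <- if (isTRUE(meta$integral)) round(data * maxval)
          else data * maxval / maxval * meta$scale + meta$offset
  movie_stack(data, meta$channel_labels, meta$pixel_size_um,
              meta$frame_interval_s)
}

#' Write intensity traces to CSV
#'
#' Columns: `time_s`, then one column per channel label. All traces must
#' share an identical time base.
#'
#' @param traces list of [roi_trace()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (!length(traces)) stopf("no traces to write")
  t0 <- traces[[1]]$times
  for (tr in traces) {
    stopifnot(inherits(tr, "roi_trace"))
    if (length(tr$times) != length(t0) || max(abs(tr$times - t0)) > 1e-9)
      stopf("traces must share a common time base")
  }
  df <- data.frame(time_s = t0)
  for (tr in traces) df[[tr$channel_label]] <- tr$values
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read intensity traces from CSV
#'
#' The file must have a `time_s` column with strictly increasing, uniformly
#' spaced values; every other column becomes one [roi_trace()]. Malformed
#' files (gaps in time, empty, ragged) are rejected.
#'
#' @param path CSV path.
#' @return named list of [roi_trace()] objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stopf("trace file '%s' is empty", path)
  if (!"time_s" %in% names(df)) stopf("trace file must have a 'time_s' column")
  if (ncol(df) < 2L) stopf("trace file has no channel columns")
  times <- df$time_s
  dt <- diff(times)
  if (any(dt <= 0)) stopf("time_s must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stopf("non-uniform time_s: a gap or irregular sampling was detected")
  chans <- setdiff(names(df), "time_s")
  out <- lapply(chans, function(ch) {
    if (any(is.na(df[[ch]]))) stopf("column '%s' has missing values", ch)
    roi_trace(times, df[[ch]], channel_label = ch)
  })
  names(out) <- chans
  out
}

#' Write / read a cell track as CSV
#'
#' @param trk a [track()].
#' @param path CSV path (columns `time_s`, `x_um`, `y_um`).
#' @return `path` (write) or a [track()] (read).
#' @export
write_track <- function(trk, path) {
  stopifnot(inherits(trk, "track"))
  utils::write.csv(format(as.data.frame(trk), digits = 15,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path)
  if (!nrow(df)) stopf("track file '%s' is empty", path)
  for (f in c("time_s", "x_um", "y_um"))
    if (is.null(df[[f]])) stopf("track file is missing column '%s'", f)
  track(df$time_s, df$x_um, df$y_um)
}

#' Write / read simulation ground truth as JSON
#'
#' The round trip is lossless: all numeric parameters are serialized at full
#' precision.
#'
#' @param truth a `sim_ground_truth` from [simulate_wave_movie()].
#' @param path JSON path.
#' @return `path` (write) or a `sim_ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  simp <- function(v) if (is.list(v)) unlist(v) else v
  x <- raw
  for (f in c("grid_shape", "pixel_size", "frame_interval", "n_frames",
              "true_period", "true_speed", "source", "direction",
              "noise_sigma", "shot_noise", "seed"))
    x[[f]] <- simp(raw[[f]])
  x$channels <- lapply(raw$channels, lapply, simp)
  x$punctum <- lapply(raw$punctum, function(p) {
    p <- lapply(p, function(v)
      if (is.list(v) && !is.null(names(v)) && "time_s" %in% names(v))
        as.data.frame(lapply(v, simp)) else simp(v))
    p
  })
  x$frap <- lapply(raw$frap, lapply, simp)
  class(x) <- "sim_ground_truth"
  x
}

#' Write / read an ROI or line definition as JSON
#'
#' @param x a [roi()] or [line_spec()].
#' @param path JSON path.
#' @return `path` (write) or the reconstructed object (read).
#' @export
write_geometry <- function(x, path) {
  if (inherits(x, "roi")) {
    jsonlite::write_json(c(list(type = "roi"), unclass(x)), path,
                         auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "line_spec")) {
    jsonlite::write_json(list(type = "line", from = x$from, to = x$to,
                              averaging_width = x$averaging_width),
                         path, auto_unbox = TRUE, digits = NA)
  } else stopf("unsupported geometry object")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(x$type %||% "",
         roi = roi(x$row0, x$col0, x$height, x$width),
         line = line_spec(x$from, x$to, x$averaging_width),
         stopf("unknown geometry type in '%s'", path))
}
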