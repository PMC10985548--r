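# End-to-end orchestration: simulate to files, analyze a movie or trace set
# against a reference channel, summarize groups of cells.

#' Simulate a movie and write all artifacts to disk
#'
#' Renders [simulate_wave_movie()], then writes the TIFF stack with its JSON
#' sidecar, the ground truth JSON, and the centre-ROI traces CSV, plus a
#' small manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param events list of [event_spec()]s.
#' @return named list of written paths, invisibly.
#' @export
simulate_to_files <- function(config, out_dir, events = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_wave_movie(config, events)
  paths <- list(
    stack = file.path(out_dir, "movie.tif"),
    truth = file.path(out_dir, "ground_truth.json"),
    traces = file.path(out_dir, "traces.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_stack(sim$stack, paths$stack)
  write_ground_truth(sim$truth, paths$truth)
  write_traces(simulate_traces(config), paths$traces)
  jsonlite::write_json(
    list(files = lapply(paths[1:3], basename), seed = config$seed,
         n_channels = length(sim$stack$channel_labels)),
    paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}

#' Analyze a set of single-cell traces against a reference channel
#'
#' Runs the full per-cell quantification: each channel is detrended and
#' called ([call_wave()]); for each probe channel the lag relative to the
#' reference is estimated both by cross-correlation and from the
#' peak-aligned average profile, and the profile's asymmetry index is
#' computed. An optional tubulin-like channel is scored for anti-phase.
#'
#' @param traces named list of [roi_trace()]s (one cell, >= 2 channels).
#' @param reference label of the reference channel (e.g. the wave marker).
#' @param tubulin optional label of an anti-phase candidate channel.
#' @param window detrending window (s).
#' @param peak_ratio_min wave-calling threshold, see [classify_wave()].
#' @param profile_window width of the average-profile window (s); default
#'   the reference's dominant period.
#' @return An object of class `cell_report`: list with `calls` (named list
#'   of `wave_call`), `lags` (data.frame: channel, lag_ccf_s, lag_profile_s,
#'   peak_correlation, asymmetry_index), `profiles`, and `anti_phase`
#'   (`NULL` unless `tubulin` given).
#' @export
analyze_traces <- function(traces, reference, tubulin = NULL, window = 80,
                           peak_ratio_min = 15, profile_window = NULL) {
  if (!reference %in% names(traces))
    stopf("reference channel '%s' not found in traces", reference)
  calls <- lapply(traces, call_wave, window = window,
                  peak_ratio_min = peak_ratio_min)
  det <- lapply(calls, attr, "detrended_trace")
  ref_call <- calls[[reference]]
  lags <- NULL; profiles <- list()
  if (ref_call$is_wave) {
    peaks <- detect_cycles(det[[reference]], ref_call)
    pw <- profile_window %||% ref_call$dominant_period
    probes <- setdiff(names(traces), reference)
    rows <- lapply(probes, function(ch) {
      le <- tryCatch(cross_correlation(det[[ch]], det[[reference]],
                                       period = ref_call$dominant_period),
                     error = function(e) NULL)
      prof <- tryCatch(average_profile(det[[ch]], peaks, pw),
                       error = function(e) NULL)
      if (!is.null(prof)) profiles[[ch]] <<- prof
      pl <- if (!is.null(prof)) profile_lag(prof) else NULL
      asym <- if (!is.null(prof)) asymmetry_index(prof) else NULL
      data.frame(channel = ch,
                 lag_ccf_s = if (!is.null(le)) le$lag else NA_real_,
                 lag_profile_s = if (!is.null(pl) && pl$status == "ok")
                   pl$lag else NA_real_,
                 peak_correlation = if (!is.null(le)) le$peak_correlation
                   else NA_real_,
                 asymmetry_index = if (!is.null(asym)) asym$index else NA_real_)
    })
    lags <- do.call(rbind, rows)
  }
  anti <- NULL
  if (!is.null(tubulin)) {
    if (!tubulin %in% names(traces))
      stopf("tubulin channel '%s' not found in traces", tubulin)
    anti <- tryCatch(
      anti_phase_score(traces[[tubulin]], traces[[reference]], window = window),
      error = function(e) list(error = conditionMessage(e)))
  }
  structure(list(calls = calls, lags = lags, profiles = profiles,
                 anti_phase = anti, reference = reference),
            class = "cell_report")
}

#' @export
print.cell_report <- function(x, ...) {
  nw <- sum(vapply(x$calls, `[[`, logical(1), "is_wave"))
  cat(sprintf("cell_report: %d/%d channels wave-positive (reference '%s')\n",
              nw, length(x$calls), x$reference))
  if (!is.null(x$lags)) print(x$lags)
  if (!is.null(x$anti_phase) && is.null(x$anti_phase$error))
    cat(sprintf("  anti-phase: r0 = %.2f, lag fraction %.2f -> %s\n",
                x$anti_phase$zero_lag_correlation, x$anti_phase$lag_fraction,
                if (x$anti_phase$anti_phase) "anti-phased" else "not anti-phased"))
  invisible(x)
}

#' Analyze a movie stack at one ROI
#'
#' Extracts one trace per channel at the ROI and runs [analyze_traces()].
#'
#' @param stack a [movie_stack()].
#' @param roi a [roi()]; default 20x20 px at the image centre.
#' @param reference reference channel label.
#' @param ... passed to [analyze_traces()].
#' @return A `cell_report`.
#' @export
analyze_movie <- function(stack, roi = NULL, reference, ...) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  if (is.null(roi))
    roi <- roi(max(0L, d[3] %/% 2L - 10L), max(0L, d[4] %/% 2L - 10L),
               min(20L, d[3]), min(20L, d[4]))
  traces <- lapply(stack$channel_labels, function(ch)
    extract_roi_trace(stack, roi, ch))
  names(traces) <- stack$channel_labels
  analyze_traces(traces, reference, ...)
}

#' Summarize wave fractions across condition groups
#'
#' @param calls_by_group named list: for each condition, a list of
#'   `wave_call`s (one per cell).
#' @param experiment_by_group optional named list of experiment assignments
#'   matching `calls_by_group`.
#' @param comparisons list of group-name pairs for Sidak-adjusted pairwise
#'   tests (on per-experiment fractions); default all pairs against the
#'   first group.
#' @return list with `stats` (list of `group_stat`), `table` (data.frame)
#'   and `tests` (from [anova_sidak()], `NULL` when fewer than 2 groups
#'   have >= 2 experiments).
#' @export
summarize_wave_fractions <- function(calls_by_group,
                                     experiment_by_group = NULL,
                                     comparisons = NULL) {
  gs <- lapply(names(calls_by_group), function(g) {
    ex <- if (!is.null(experiment_by_group)) experiment_by_group[[g]]
          else rep(1L, length(calls_by_group[[g]]))
    wave_fraction(calls_by_group[[g]], ex, label = g)
  })
  names(gs) <- names(calls_by_group)
  tab <- do.call(rbind, lapply(gs, function(s)
    data.frame(group = s$label, mean_fraction = s$mean_fraction, sem = s$sem,
               n_cells = s$n_cells, n_experiments = s$n_experiments)))
  rownames(tab) <- NULL
  eligible <- names(gs)[vapply(gs, function(s) s$n_experiments >= 2, logical(1))]
  tests <- NULL
  if (length(eligible) >= 2) {
    fr <- lapply(gs[eligible], `[[`, "fractions")
    if (is.null(comparisons))
      comparisons <- lapply(eligible[-1], function(g) c(eligible[1], g))
    tests <- anova_sidak(fr, comparisons)
  }
  list(stats = gs, table = tab, tests = tests)
}
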