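# Population-level summaries: per-experiment wave fractions with SEM,
# unpaired t-tests, one-way ANOVA with Sidak-adjusted pairwise comparisons,
# and wave-frequency histograms.

#' Fraction of wave-positive cells, per experiment
#'
#' A cell counts as wave-positive only when `is_wave` is `TRUE` *and*
#' polarity is positive: negative waves (intensity dips below baseline) are
#' grouped with non-waves, as they may reflect membrane fluctuations rather
#' than travelling waves. The fraction is computed per independent
#' experiment; the reported error is the SEM across experiments (not the
#' binomial error across cells), which is how biological replicates are
#' conventionally summarized. The binomial SEM across all cells is offered
#' as a secondary field.
#'
#' @param calls list of `wave_call` objects, one per cell.
#' @param experiment vector (same length) assigning each cell to an
#'   experiment.
#' @param label group label for reporting.
#' @return An object of class `group_stat`: list with `label`, `fractions`
#'   (per experiment), `mean_fraction`, `sem` (`NA` for a single
#'   experiment), `sem_binomial`, `n_experiments`, `n_cells`.
#' @export
wave_fraction <- function(calls, experiment = rep(1L, length(calls)),
                          label = "group") {
  if (!length(calls)) stopf("no calls supplied")
  if (length(experiment) != length(calls))
    stopf("`experiment` must match `calls` in length")
  pos <- vapply(calls, function(cl) {
    stopifnot(inherits(cl, "wave_call"))
    isTRUE(cl$is_wave) && identical(cl$polarity, "positive")
  }, logical(1))
  ex <- factor(experiment)
  counts <- table(ex)
  if (any(counts == 0)) stopf("empty experiment group")
  fractions <- as.numeric(tapply(pos, ex, mean))
  k <- length(fractions)
  p_all <- mean(pos)
  structure(list(label = label, fractions = fractions,
                 mean_fraction = mean(fractions),
                 sem = if (k >= 2) stats::sd(fractions) / sqrt(k) else NA_real_,
                 sem_binomial = sqrt(p_all * (1 - p_all) / length(pos)),
                 n_experiments = k, n_cells = length(calls)),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("group_stat '%s': %.1f%% wave-positive (SEM %s), %d cells, %d experiment(s)\n",
              x$label, 100 * x$mean_fraction,
              if (is.na(x$sem)) "undefined" else sprintf("%.1f%%", 100 * x$sem),
              x$n_cells, x$n_experiments))
  invisible(x)
}

#' Unpaired two-sample t-test (equal variance, two-sided)
#'
#' Classical Student's t comparing per-cell values between two conditions.
#' When both groups are degenerate (zero variance) with equal means, p = 1
#' is returned with a flag instead of an error.
#'
#' @param a,b numeric vectors of per-cell values, each of length >= 2.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`, `flag`.
#' @export
compare_two <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b),
                  flag = "degenerate_variance"))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b),
                flag = "degenerate_variance"))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_a = mean(a), mean_b = mean(b), flag = NULL)
}

#' One-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' Overall one-way ANOVA across all groups, followed by unpaired
#' equal-variance t-tests for the *requested* pairs only, each p-value
#' adjusted by the Sidak correction over the m requested comparisons:
#' `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param comparisons list of length-2 character vectors naming group pairs
#'   to compare; empty for the overall ANOVA only.
#' @return list with `F`, `p_overall`, `df`, and `pairwise` (data.frame with
#'   columns `a`, `b`, `t`, `p`, `p_adj`).
#' @export
anova_sidak <- function(groups, comparisons = list()) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stopf("groups must be named")
  for (g in groups) if (length(g) < 2) stopf("each group needs >= 2 values")
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  m <- length(comparisons)
  pair <- NULL
  if (m > 0) {
    rows <- lapply(comparisons, function(cmp) {
      if (length(cmp) != 2 || !all(cmp %in% names(groups)))
        stopf("each comparison must name two existing groups")
      tt <- compare_two(groups[[cmp[1]]], groups[[cmp[2]]])
      data.frame(a = cmp[1], b = cmp[2], t = tt$t, p = tt$p,
                 p_adj = sidak_adjust(tt$p, m))
    })
    pair <- do.call(rbind, rows)
  }
  list(F = an[["F value"]][1], p_overall = an[["Pr(>F)"]][1],
       df = an[["Df"]], pairwise = pair)
}

#' Sidak multiple-comparison adjustment
#'
#' @param p raw p-value(s).
#' @param m number of comparisons in the family.
#' @return `1 - (1 - p)^m`, capped at 1.
#' @export
sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Histogram of dominant wave frequencies
#'
#' Bins `1 / dominant_period` of wave-positive calls. Calls falling outside
#' the edge range are counted in open-ended boundary bins and flagged.
#'
#' @param calls list of `wave_call` objects; non-waves are ignored.
#' @param breaks ascending bin edges in Hz.
#' @return An object of class `frequency_histogram`: list with `breaks`,
#'   `counts`, `n`, `out_of_range`.
#' @export
frequency_histogram <- function(calls, breaks) {
  if (any(diff(breaks) <= 0)) stopf("breaks must be strictly ascending")
  freqs <- vapply(Filter(function(cl) isTRUE(cl$is_wave), calls),
                  function(cl) 1 / cl$dominant_period, numeric(1))
  oor <- sum(freqs < breaks[1] | freqs >= breaks[length(breaks)])
  cuts <- findInterval(freqs, breaks, rightmost.closed = FALSE)
  cuts <- pmin(pmax(cuts, 1L), length(breaks) - 1L)  # open end bins
  counts <- tabulate(cuts, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts, n = length(freqs),
                 out_of_range = oor),
            class = "frequency_histogram")
}

#' @export
print.frequency_histogram <- function(x, ...) {
  cat(sprintf("frequency_histogram: %d wave(s) in %d bins (%g..%g Hz)%s\n",
              x$n, length(x$counts), min(x$breaks), max(x$breaks),
              if (x$out_of_range) sprintf(", %d out of range", x$out_of_range) else ""))
  invisible(x)
}
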