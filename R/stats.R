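#' Two-tier summary statistics for chirality quantities
#'
#' Chirality analyses produce large per-trial samples (voxels, pixels,
#' steps) and a handful of trials (cells, cultures). The per-trial tier
#' reports mean +/- s.d. and a two-sided Wilcoxon signed-rank test of the
#' median against zero; the across-trial tier takes the means of the
#' trials and applies a two-sided one-sample t-test against zero,
#' reporting mean +/- s.e.m. of the means.
#'
#' @name stats_report
NULL

#' Per-trial summary with a signed-rank test against zero
#'
#' Zero values are dropped before the Wilcoxon signed-rank test (the
#' classical zero-handling policy); the normal approximation is used for
#' n > 25. An all-zero sample has no evidence either way: p is reported as
#' 1 with `degenerate = TRUE`.
#'
#' @param values numeric vector (n >= 5 for a meaningful test).
#' @param label quantity name carried into the output row.
#' @return One-row data.frame: label, n, mean, sd, p_wilcoxon, degenerate.
#' @export
trial_summary <- function(values, label = "value") {
  values <- values[is.finite(values)]
  n <- length(values)
  degenerate <- all(values == 0)
  p <- 1
  if (!degenerate && n >= 1) {
    nz <- values[values != 0]
    p <- suppressWarnings(stats::wilcox.test(
      nz, mu = 0, exact = length(nz) <= 25)$p.value)
  }
  data.frame(label = label, n = n, mean = mean(values),
             sd = stats::sd(values), p_wilcoxon = p,
             degenerate = degenerate)
}

#' Across-trial one-sample t-test of the trial means
#'
#' @param trial_means numeric vector of per-trial means (>= 3 trials).
#' @return One-row data.frame: n_trials, mean_of_means, sem, t, df, p_t,
#'   zero_variance flag (infinite t).
#' @export
across_trial_test <- function(trial_means) {
  trial_means <- trial_means[is.finite(trial_means)]
  n <- length(trial_means)
  if (n < 3) stop("need at least 3 trials")
  m <- mean(trial_means)
  s <- stats::sd(trial_means)
  sem <- s / sqrt(n)
  zero_var <- s == 0
  tstat <- if (zero_var) sign(m) * Inf else m / sem
  p <- if (zero_var) (if (m == 0) 1 else 0) else
    2 * stats::pt(-abs(tstat), df = n - 1)
  data.frame(n_trials = n, mean_of_means = m, sem = sem, t = tstat,
             df = n - 1, p_t = p, zero_variance = zero_var)
}

#' Histogram counts and edges for export
#'
#' Fixed-width bins over `range` (default the data range); values on the
#' right edge of the last bin are included, so counts always sum to n.
#'
#' @param values numeric vector (non-empty).
#' @param bins number of bins (>= 2).
#' @param range optional `c(lo, hi)` bin range; values outside are
#'   clamped into the boundary bins.
#' @return List with `counts` (length `bins`) and `edges`
#'   (length `bins + 1`).
#' @export
histogram_export <- function(values, bins = 32, range = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty input")
  stopifnot(bins >= 2)
  if (is.null(range)) range <- base::range(values)
  if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), bins)
  list(counts = tabulate(idx, bins), edges = edges)
}
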