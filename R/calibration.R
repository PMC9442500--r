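#' Score-frequency histogram
#'
#' Bins a collection of similarity scores into \code{n_bins} equal-width
#' bins spanning the metric's score range (by default 100 bins, e.g. over
#' [0, 1] for most metrics, [0, 2] for Manhattan) and normalises the bin
#' counts by the number of scores. Bins are left-closed right-open; the
#' last bin is closed so scores exactly at the range maximum are kept.
#' Scores outside the range are clipped into the end bins with a warning.
#'
#' Two histograms are typically compared: the all-scores distribution
#' (every query-reference pair, dominated by negatives) and the
#' positive-only distribution (truth-set pairs only).
#'
#' @param scores Numeric vector of scores (at least one).
#' @param metric Metric acronym, used to pick the score range; or
#'   \code{NULL} when \code{range} is given directly.
#' @param n_bins Number of bins.
#' @param range Score range (overrides the metric's declared range).
#' @return Object of class \code{score_histogram}: \code{metric},
#'   \code{n_bins}, \code{range}, \code{breaks}, \code{freqs} (sums to 1),
#'   \code{n_scores}.
#' @export
build_histogram <- function(scores, metric = NULL, n_bins = 100L,
                            range = NULL) {
  if (length(scores) == 0L) stop("empty score collection")
  if (is.null(range)) {
    if (is.null(metric)) stop("provide a metric or an explicit range")
    range <- metric_info(metric)$range
    if (!all(is.finite(range)))
      stop("metric '", metric, "' has an unbounded score range; ",
           "pass an explicit range")
  }
  lo <- range[1]; hi <- range[2]
  stopifnot(hi > lo)
  if (any(scores < lo) || any(scores > hi)) {
    warning("scores outside [", lo, ", ", hi, "] clipped into end bins")
    scores <- pmin(pmax(scores, lo), hi)
  }
  width <- (hi - lo) / n_bins
  idx <- pmin(n_bins, floor((scores - lo) / width) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(metric = if (is.null(metric)) NA_character_ else metric,
                 n_bins = as.integer(n_bins),
                 range = c(lo, hi),
                 breaks = seq(lo, hi, length.out = n_bins + 1L),
                 freqs = counts / length(scores),
                 n_scores = length(scores)),
            class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  cat("<score_histogram> ", x$n_scores, " scores in ", x$n_bins,
      " bins over [", x$range[1], ", ", round(x$range[2], 4), "]\n",
      sep = "")
  invisible(x)
}

check_same_binning <- function(a, b) {
  if (a$n_bins != b$n_bins || !isTRUE(all.equal(a$range, b$range)))
    stop("histograms have different binning")
}

#' Overlapping index between two score distributions
#'
#' \eqn{\eta(A,B) = \sum_s \min[f_A(s), f_B(s)]} over the shared bins:
#' 1 for identical distributions, 0 for disjoint supports. A small overlap
#' between the positive-only and the all-scores distribution indicates
#' that a metric separates true from false pairs well, so high predictive
#' accuracy can be expected; an overlap near 1 predicts poor accuracy.
#'
#' @param a,b \code{\link{build_histogram}} objects with identical binning.
#' @return Numeric in [0, 1].
#' @examples
#' h1 <- build_histogram(runif(100, 0, 0.3), range = c(0, 1))
#' h2 <- build_histogram(runif(100, 0.7, 1), range = c(0, 1))
#' overlapping_index(h1, h2)  # 0: disjoint supports
#' @export
overlapping_index <- function(a, b) {
  check_same_binning(a, b)
  sum(pmin(a$freqs, b$freqs))
}

#' Cumulative-difference cut-off selection
#'
#' Accumulates both histograms over the score range and takes the per-bin
#' difference of the cumulative curves, positives minus all-scores. Because
#' true-pair scores concentrate at the similar (low) end while the
#' all-scores mass sits higher, the difference rises then falls back to 0;
#' its maximum marks the score below which most positives but few negatives
#' lie. The upper edge of the first bin attaining the maximum is returned
#' as the cut-off score; applying it as a filter (retain score <= cut-off)
#' enriches for true positives at the cost of discarding some.
#'
#' @param all_scores Histogram of every comparison's score.
#' @param positives Histogram of truth-set pair scores, same binning.
#' @return Object of class \code{cumulative_difference}: \code{breaks},
#'   \code{cum_pos}, \code{cum_all} (each non-decreasing to 1),
#'   \code{diff} (= cum_pos - cum_all) and \code{cutoff_score}.
#' @export
cumulative_difference <- function(all_scores, positives) {
  check_same_binning(all_scores, positives)
  cum_all <- cumsum(all_scores$freqs)
  cum_pos <- cumsum(positives$freqs)
  d <- cum_pos - cum_all
  peak <- which.max(d)       # first bin attaining the maximum
  structure(list(breaks = all_scores$breaks,
                 cum_pos = cum_pos, cum_all = cum_all, diff = d,
                 cutoff_score = all_scores$breaks[peak + 1L]),
            class = "cumulative_difference")
}

#' @export
print.cumulative_difference <- function(x, ...) {
  cat("<cumulative_difference> cutoff score ",
      format(x$cutoff_score), " (peak difference ",
      round(max(x$diff), 4), ")\n", sep = "")
  invisible(x)
}

#' Accuracy-vs-cutoff calibration curve
#'
#' For a set of top hits (one best-scoring reference per query) labelled
#' true/false by an objective function, evaluates on a grid of candidate
#' cut-off scores \eqn{s}: the fraction of retained hits (score <= s) that
#' are true, and the fraction of all true hits excluded by the cut-off.
#' The first curve maps a score onto the probability that a prediction at
#' that threshold is correct; the second shows the recall cost. The score
#' range is partitioned into three regions: \code{high} where the accuracy
#' is at least \code{high_accuracy}, \code{low} for scores above the point
#' where at least \code{pos_coverage} of the true hits already lie below
#' (scores there are unlikely to be true), and \code{variable} in between.
#'
#' @param hits \code{score_records} with one row per query (see
#'   \code{\link{top_hits}}), or any data frame with \code{query_id},
#'   \code{ref_id}, \code{score}.
#' @param truth A \code{\link{truth_pairs}} or \code{\link{truth_taxonomy}}
#'   object labelling each (query_id, ref_id) pair.
#' @param grid_size Number of grid points over the score range.
#' @param range Score range; defaults to the metric range carried by
#'   \code{hits} or [0, 1].
#' @param high_accuracy Accuracy threshold of the high region.
#' @param pos_coverage Positive-coverage threshold of the low region.
#' @return Object of class \code{calibration_curve}: \code{grid},
#'   \code{frac_correct}, \code{frac_excluded}, \code{region} (factor per
#'   grid point), \code{overall_accuracy}, \code{n_hits}, \code{n_true}.
#' @export
calibration_curve <- function(hits, truth, grid_size = 100L,
                              range = NULL, high_accuracy = 0.95,
                              pos_coverage = 0.99) {
  if (nrow(hits) == 0L) stop("empty top-hit set")
  if (anyDuplicated(hits$query_id))
    stop("calibration_curve() expects one record per query")
  if (is.null(range)) {
    m <- attr(hits, "metric")
    range <- if (!is.null(m)) metric_info(m)$range else c(0, 1)
  }
  lab <- is_positive(truth, hits$query_id, hits$ref_id)
  n_true <- sum(lab)
  grid <- seq(range[1], range[2], length.out = grid_size + 1L)[-1L]
  frac_correct <- numeric(grid_size)
  frac_excluded <- numeric(grid_size)
  for (g in seq_along(grid)) {
    retained <- hits$score <= grid[g]
    n_ret <- sum(retained)
    frac_correct[g] <- if (n_ret > 0L) sum(lab & retained) / n_ret else 0
    frac_excluded[g] <- if (n_true > 0L) sum(lab & !retained) / n_true
                        else 0
  }
  region <- ifelse(frac_correct >= high_accuracy, "high",
            ifelse(frac_excluded <= 1 - pos_coverage, "low", "variable"))
  # precedence: a grid point that is both accurate and past the positive
  # mass stays "high"
  structure(list(grid = grid,
                 frac_correct = frac_correct,
                 frac_excluded = frac_excluded,
                 region = factor(region,
                                 levels = c("high", "variable", "low")),
                 overall_accuracy = mean(lab),
                 n_hits = nrow(hits), n_true = n_true,
                 range = range),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> ", x$n_hits, " top hits, ", x$n_true,
      " true; overall accuracy ", round(x$overall_accuracy, 4), "\n",
      sep = "")
  invisible(x)
}

#' Map a score onto a probability of correct prediction
#'
#' Looks up the calibration curve at the grid point covering the score
#' (step interpolation, no extrapolation) and returns the fraction-correct
#' value there as the probability that a prediction with this score is
#' true, together with the region label (\code{high} / \code{variable} /
#' \code{low}).
#'
#' @param score Numeric score(s) within the curve's range.
#' @param curve A \code{\link{calibration_curve}}.
#' @return Data frame with columns \code{score}, \code{probability},
#'   \code{region}.
#' @export
score_to_probability <- function(score, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(score < curve$range[1]) || any(score > curve$range[2]))
    stop("score outside the calibrated range [",
         curve$range[1], ", ", curve$range[2], "]")
  # first grid point >= score covers it (grid points are bin upper edges)
  idx <- findInterval(score, curve$grid, left.open = TRUE) + 1L
  idx <- pmin(idx, length(curve$grid))
  data.frame(score = score,
             probability = curve$frac_correct[idx],
             region = as.character(curve$region[idx]),
             stringsAsFactors = FALSE)
}

#' Annotate a result table with probabilities and regions
#'
#' Convenience wrapper that appends \code{probability} and \code{region}
#' columns to a blastlike result table using a fitted calibration curve.
#'
#' @param records \code{score_records} data frame.
#' @param curve A \code{\link{calibration_curve}}.
#' @return The input data frame with two extra columns.
#' @export
annotate_probabilities <- function(records, curve) {
  ann <- score_to_probability(records$score, curve)
  records$probability <- ann$probability
  records$region <- ann$region
  records
}
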