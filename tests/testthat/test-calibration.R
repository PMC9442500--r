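test_that("histograms bin correctly and normalise to one", {
  h <- build_histogram(rep(0.005, 3), "ngd")
  expect_identical(h$n_bins, 100L)
  expect_equal(h$freqs[1], 1)
  expect_equal(sum(h$freqs), 1)
  # one score per bin -> uniform frequencies
  grid <- seq(0.005, 0.995, by = 0.01)
  hu <- build_histogram(grid, "ngd")
  expect_equal(hu$freqs, rep(0.01, 100))
  # a score exactly at the top of the range lands in the last bin
  ht <- build_histogram(c(0, 1), "ngd")
  expect_equal(ht$freqs[c(1, 100)], c(0.5, 0.5))
  # Manhattan range reaches 2
  hm <- build_histogram(c(1.99), "manh")
  expect_equal(hm$range, c(0, 2))
  expect_equal(hm$freqs[100], 1)
  expect_error(build_histogram(numeric(0), "ngd"), "empty")
  expect_warning(build_histogram(c(0.5, 1.7), "ngd"), "clipped")
})

test_that("histogram of a known generator matches its pmf", {
  set.seed(42)
  x <- stats::rbeta(10000, 2, 5)
  h <- build_histogram(x, range = c(0, 1), n_bins = 100L)
  p <- diff(stats::pbeta(h$breaks, 2, 5))
  # each bin within 3 multinomial standard errors
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(h$freqs - p) <= 3 * se + 1e-12))
})

test_that("overlapping index is a proper overlap measure", {
  a <- build_histogram(runif(500, 0, 0.4), range = c(0, 1))
  b <- build_histogram(runif(500, 0.6, 1), range = c(0, 1))
  expect_equal(overlapping_index(a, a), 1)
  expect_equal(overlapping_index(a, b), 0)   # disjoint supports
  expect_equal(overlapping_index(a, b), overlapping_index(b, a))
  # hand example on a two-bin histogram
  h1 <- build_histogram(c(0.2, 0.8), range = c(0, 1), n_bins = 2L)
  h2 <- build_histogram(c(0.2, 0.8, 0.9, 0.7), range = c(0, 1),
                        n_bins = 2L)
  # freqs [0.5, 0.5] vs [0.25, 0.75]
  expect_equal(overlapping_index(h1, h2), 0.75)
  expect_error(overlapping_index(a, h1), "binning")
})

test_that("moving mass from shared to disjoint bins lowers the overlap", {
  set.seed(10)
  base <- runif(400, 0, 0.5)
  a <- build_histogram(base, range = c(0, 1))
  prev <- overlapping_index(a, build_histogram(base, range = c(0, 1)))
  for (frac in c(0.25, 0.5, 0.75)) {
    moved <- base
    idx <- seq_len(400 * frac)
    moved[idx] <- runif(length(idx), 0.5, 1)   # disjoint territory
    eta <- overlapping_index(a, build_histogram(moved, range = c(0, 1)))
    expect_lt(eta, prev + 1e-12)
    prev <- eta
  }
})

test_that("cumulative difference peaks where positives separate", {
  # hand example: pos = [0.9, 0.1], all = [0.2, 0.8] over two bins
  pos <- build_histogram(c(rep(0.2, 9), 0.8), range = c(0, 1), n_bins = 2L)
  all <- build_histogram(c(rep(0.2, 2), rep(0.8, 8)), range = c(0, 1),
                         n_bins = 2L)
  cd <- cumulative_difference(all, pos)
  expect_equal(cd$cum_pos, c(0.9, 1.0))
  expect_equal(cd$cum_all, c(0.2, 1.0))
  expect_equal(cd$diff, c(0.7, 0.0))
  expect_equal(cd$cutoff_score, 0.5)
  # identical distributions: flat difference, first-max rule picks bin 1
  cd0 <- cumulative_difference(all, all)
  expect_true(all(abs(cd0$diff) < 1e-12))
  expect_equal(cd0$cutoff_score, 0.5)
  # cumulative curves are non-decreasing and end at 1
  expect_true(all(diff(cd$cum_pos) >= 0))
  expect_equal(cd$cum_all[length(cd$cum_all)], 1)
})

test_that("two-bump score mixture puts the cutoff in the gap", {
  set.seed(21)
  pos_scores <- runif(2000, 0.05, 0.35)
  neg_scores <- runif(18000, 0.55, 0.95)
  all_h <- build_histogram(c(pos_scores, neg_scores), range = c(0, 1))
  pos_h <- build_histogram(pos_scores, range = c(0, 1))
  cd <- cumulative_difference(all_h, pos_h)
  expect_gte(cd$cutoff_score, 0.35)
  expect_lte(cd$cutoff_score, 0.56)
})

test_that("calibration curve reproduces the hand-counted toy example", {
  hits <- structure(data.frame(
    query_id = paste0("q", 1:4),
    ref_id = c("r1", "r2", "r3", "r4"),
    score = c(0.1, 0.2, 0.6, 0.9), rank = 1L),
    class = c("score_records", "data.frame"))
  truth <- truth_pairs(data.frame(id_a = c("q1", "q2"),
                                  id_b = c("r1", "r2")))
  curve <- suppressWarnings(calibration_curve(hits, truth, grid_size = 10L,
                             range = c(0, 1)))
  p5 <- score_to_probability(0.5, curve)
  expect_equal(p5$probability, 1.0)
  at_half <- which(abs(curve$grid - 0.5) < 1e-9)
  expect_equal(curve$frac_excluded[at_half], 0)
  expect_equal(curve$frac_correct[length(curve$grid)], 0.5)
  expect_equal(curve$frac_excluded[length(curve$grid)], 0)
  expect_equal(curve$overall_accuracy, 0.5)
  # a score below every positive still maps to the covering grid point
  expect_equal(score_to_probability(0.05, curve)$probability, 1.0)
  # where nothing at all is retained the convention is 0
  fine <- suppressWarnings(calibration_curve(hits, truth, grid_size = 100L,
                            range = c(0, 1)))
  expect_equal(score_to_probability(0.005, fine)$probability, 0)
  expect_error(score_to_probability(1.5, curve), "range")
})

test_that("frac_excluded decreases in s and vanishes at the range top", {
  set.seed(33)
  n <- 500
  hits <- structure(data.frame(
    query_id = paste0("q", 1:n), ref_id = paste0("r", 1:n),
    score = runif(n), rank = 1L),
    class = c("score_records", "data.frame"))
  pos_idx <- sample(n, 200)
  truth <- truth_pairs(data.frame(id_a = paste0("q", pos_idx),
                                  id_b = paste0("r", pos_idx)))
  curve <- suppressWarnings(calibration_curve(hits, truth, range = c(0, 1)))
  expect_true(all(diff(curve$frac_excluded) <= 1e-12))
  expect_equal(curve$frac_excluded[length(curve$grid)], 0)
  expect_equal(curve$frac_correct[length(curve$grid)],
               curve$overall_accuracy)
})

test_that("the calibration chain recovers a known posterior", {
  # two-population generator: positives score low, negatives high, with
  # known overlap; the curve's frac_correct at threshold s must match the
  # analytic P(positive | score <= s)
  set.seed(77)
  n <- 10000
  prior <- 0.3
  is_pos <- runif(n) < prior
  score <- ifelse(is_pos, rbeta(n, 2, 8), rbeta(n, 8, 2))
  hits <- structure(data.frame(
    query_id = paste0("q", 1:n), ref_id = paste0("r", 1:n),
    score = score, rank = 1L),
    class = c("score_records", "data.frame"))
  truth <- truth_pairs(data.frame(id_a = paste0("q", which(is_pos)),
                                  id_b = paste0("r", which(is_pos))))
  curve <- suppressWarnings(calibration_curve(hits, truth, range = c(0, 1)))
  for (s in c(0.2, 0.4, 0.6, 0.8)) {
    post <- prior * pbeta(s, 2, 8) /
      (prior * pbeta(s, 2, 8) + (1 - prior) * pbeta(s, 8, 2))
    got <- score_to_probability(s, curve)$probability
    n_ret <- sum(score <= s)
    mc_se <- sqrt(post * (1 - post) / n_ret)
    expect_lt(abs(got - post), 4 * mc_se + 0.01)
  }
  # applying the histogram-selected cutoff raises precision, lowers recall
  all_h <- build_histogram(score, range = c(0, 1))
  pos_h <- build_histogram(score[is_pos], range = c(0, 1))
  cut <- cumulative_difference(all_h, pos_h)$cutoff_score
  kept <- score <= cut
  precision_cut <- mean(is_pos[kept])
  recall_cut <- sum(is_pos & kept) / sum(is_pos)
  expect_gt(precision_cut, mean(is_pos))   # enriched over no cutoff
  expect_lt(recall_cut, 1)                 # at a recall cost
  expect_gt(recall_cut, 0.5)               # but keeps most positives
})

test_that("regions partition the score range as high/variable/low", {
  set.seed(5)
  n <- 2000
  is_pos <- runif(n) < 0.5
  score <- ifelse(is_pos, rbeta(n, 2, 5), rbeta(n, 5, 2))
  hits <- structure(data.frame(
    query_id = paste0("q", 1:n), ref_id = paste0("r", 1:n),
    score = score, rank = 1L),
    class = c("score_records", "data.frame"))
  truth <- truth_pairs(data.frame(id_a = paste0("q", which(is_pos)),
                                  id_b = paste0("r", which(is_pos))))
  curve <- suppressWarnings(calibration_curve(hits, truth, range = c(0, 1)))
  regions <- as.character(curve$region)
  expect_identical(regions[1], "high")          # low scores: pure positives
  expect_identical(regions[length(regions)], "low")
  expect_true("variable" %in% regions)
  # regions appear in order high -> variable -> low along the grid
  expect_identical(rle(regions)$values, c("high", "variable", "low"))
  ann <- annotate_probabilities(hits, curve)
  expect_true(all(c("probability", "region") %in% names(ann)))
})
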