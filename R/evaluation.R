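#' Objective function from a table of known pairs
#'
#' An objective function restores the biological context lost in
#' alignment-free scoring: it maps a pair of sequence identifiers onto
#' external knowledge (here, a table of known positive pairs such as
#' curated orthologs) and answers true/false. Membership is
#' order-insensitive: \code{(a, b)} and \code{(b, a)} are the same pair.
#'
#' @param pairs Data frame whose first two columns are the paired ids, or
#'   a path to a tab-separated file with two id columns (no header
#'   required; a header line is auto-detected by column names
#'   \code{id_a}/\code{id_b}).
#' @return Object of class \code{truth_set} (kind \code{pair_table}).
#' @export
truth_pairs <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1L) {
    first <- readLines(pairs, n = 1L)
    header <- grepl("^id_a\t", first)
    pairs <- utils::read.table(pairs, sep = "\t", header = header,
                               colClasses = "character")
  }
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  structure(list(kind = "pair_table",
                 pairs = data.frame(id_a = a, id_b = b,
                                    stringsAsFactors = FALSE),
                 keys = unique(pair_key(a, b))),
            class = "truth_set")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Objective function from taxonomic lineages
#'
#' Labels a pair of sequence identifiers positive when their lineages
#' agree (and are non-missing) at a chosen taxonomic rank. Lineages follow
#' the seven-level hierarchy strain < species < genus < family < order <
#' class < phylum; missing entries never match. The same score table can
#' be evaluated under different ranks (e.g. species vs genus) simply by
#' changing \code{rank}.
#'
#' @param taxonomy Data frame with an \code{id} column plus one column per
#'   rank (missing = \code{NA} or \code{""}), or a path to a tab-separated
#'   file with a header.
#' @param rank Rank at which pairs must agree.
#' @return Object of class \code{truth_set} (kind \code{taxonomy_rank}).
#' @export
truth_taxonomy <- function(taxonomy,
                           rank = c("species", "strain", "genus",
                                    "family", "order", "class",
                                    "phylum")) {
  rank <- match.arg(rank)
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- utils::read.table(taxonomy, sep = "\t", header = TRUE,
                                  colClasses = "character",
                                  na.strings = c("NA", ""))
  stopifnot(is.data.frame(taxonomy), "id" %in% names(taxonomy))
  if (!rank %in% names(taxonomy))
    stop("taxonomy table has no '", rank, "' column")
  if (anyDuplicated(taxonomy$id))
    stop("duplicate ids in taxonomy table")
  structure(list(kind = "taxonomy_rank", taxonomy = taxonomy,
                 rank = rank),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  if (x$kind == "pair_table")
    cat("<truth_set> pair table with ", length(x$keys),
        " unique pairs\n", sep = "")
  else
    cat("<truth_set> taxonomy at rank '", x$rank, "' over ",
        nrow(x$taxonomy), " ids\n", sep = "")
  invisible(x)
}

#' Evaluate the objective function on id pairs
#'
#' Total predicate: ids unknown to the truth structure yield \code{FALSE}
#' (with a warning) rather than an error, so every scored pair can be
#' labelled.
#'
#' @param truth A \code{\link{truth_pairs}} or \code{\link{truth_taxonomy}}
#'   object.
#' @param id_a,id_b Character vectors of equal length.
#' @return Logical vector.
#' @export
is_positive <- function(truth, id_a, id_b) {
  stopifnot(inherits(truth, "truth_set"), length(id_a) == length(id_b))
  if (truth$kind == "pair_table") {
    known <- unique(c(truth$pairs$id_a, truth$pairs$id_b))
    unknown <- !(id_a %in% known) & !(id_b %in% known)
    if (any(unknown))
      warning(sum(unknown), " pair(s) with ids unknown to the pair table")
    pair_key(id_a, id_b) %in% truth$keys
  } else {
    tax <- truth$taxonomy
    ia <- match(id_a, tax$id)
    ib <- match(id_b, tax$id)
    if (anyNA(ia) || anyNA(ib))
      warning(sum(is.na(ia) | is.na(ib)),
              " pair(s) with ids missing from the taxonomy")
    va <- tax[[truth$rank]][ia]
    vb <- tax[[truth$rank]][ib]
    !is.na(va) & !is.na(vb) & va == vb
  }
}

#' One-to-one reduction of a pair table
#'
#' When a query id maps to several partners (many-to-one ortholog
#' relationships), keeps only the first-listed partner for each left-side
#' id. This is the reduction used to build positive-only score
#' distributions from unique pairs.
#'
#' @param pairs Data frame whose first two columns are the paired ids, in
#'   input order.
#' @return Data frame with one row per distinct left-side id.
#' @export
unique_positive_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  out <- pairs[!duplicated(pairs[[1]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-hit accuracy
#'
#' Fraction of queries whose rank-1 reference is a true pair under the
#' objective function. Queries that have no possible true partner in the
#' reference set still count as failures, which is why the achievable
#' ceiling can be well below 1 (it equals the fraction of queries with any
#' true partner present).
#'
#' @param hits \code{score_records} with one row per query.
#' @param truth A \code{truth_set}.
#' @return Numeric in [0, 1].
#' @export
top_hit_accuracy <- function(hits, truth) {
  if (nrow(hits) == 0L) stop("empty top-hit set")
  if (anyDuplicated(hits$query_id))
    stop("top_hit_accuracy() expects one record per query")
  mean(is_positive(truth, hits$query_id, hits$ref_id))
}

#' Area under the ROC curve for distance scores
#'
#' AUC oriented for distances (true pairs should score LOW): computed as
#' the Mann-Whitney rank statistic \eqn{P(score_{pos} < score_{neg}) +
#' 0.5\,P(tie)}. 1 means perfect separation, 0.5 is random.
#'
#' @param scores Numeric scores.
#' @param positive Logical labels, same length (needs at least one
#'   \code{TRUE} and one \code{FALSE}).
#' @return Numeric in [0, 1].
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_auc() needs both positive and negative scores")
  r <- rank(scores)   # average ranks handle ties as 0.5 concordance
  (sum(r[!positive]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

#' AUC of a score table under an objective function
#'
#' @param records \code{score_records} data frame (all scored pairs, not
#'   just top hits).
#' @param truth A \code{truth_set}.
#' @return Numeric in [0, 1].
#' @export
roc_auc_records <- function(records, truth) {
  roc_auc(records$score,
          is_positive(truth, records$query_id, records$ref_id))
}

#' Spearman correlation of score with mean pair length
#'
#' Tests whether a metric's score on true pairs depends on how long the
#' sequences are: Spearman rank correlation between the mean length of
#' each pair and its score. A strongly negative rho means longer pairs get
#' systematically more-similar (lower) scores, i.e. the metric confounds
#' length with similarity.
#'
#' @param scores Numeric scores of the pairs.
#' @param mean_lengths Mean sequence length of each pair.
#' @return List with \code{rho} and \code{p_value} (two-sided).
#' @export
length_score_correlation <- function(scores, mean_lengths) {
  stopifnot(length(scores) == length(mean_lengths))
  if (length(scores) < 3L) stop("need at least 3 pairs")
  if (stats::sd(scores) == 0 || stats::sd(mean_lengths) == 0)
    stop("constant input vector")
  ct <- stats::cor.test(mean_lengths, scores, method = "spearman",
                        exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
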