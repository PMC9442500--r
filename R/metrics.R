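#' Metric roster
#'
#' The similarity/distance metrics available to the search engine. All are
#' distances (lower = more similar) except the raw D2 statistic
#' \code{d2raw}, whose value grows with sequence length and is mainly of
#' diagnostic interest. \code{ncamb} is accepted as an alias of
#' \code{ncanb}.
#'
#' @param name Metric acronym: one of \code{d2raw}, \code{d2},
#'   \code{euclid}, \code{manh}, \code{cheby}, \code{ncanb}, \code{bc},
#'   \code{ngd}, \code{d2star}, \code{d2s}.
#' @return List with \code{name}, \code{input} (\code{"counts"},
#'   \code{"freqs"} or \code{"counts+background"}), \code{range} (closed
#'   score interval) and \code{lower_is_similar}.
#' @export
metric_info <- function(name) {
  if (identical(name, "ncamb")) name <- "ncanb"
  name <- match.arg(name, c("d2raw", "d2", "euclid", "manh", "cheby",
                            "ncanb", "bc", "ngd", "d2star", "d2s"))
  info <- switch(name,
    d2raw  = list(input = "counts", range = c(0, Inf),
                  lower_is_similar = FALSE),
    d2     = list(input = "counts", range = c(0, 1),
                  lower_is_similar = TRUE),
    euclid = list(input = "freqs", range = c(0, sqrt(2)),
                  lower_is_similar = TRUE),
    manh   = list(input = "freqs", range = c(0, 2),
                  lower_is_similar = TRUE),
    cheby  = list(input = "freqs", range = c(0, 1),
                  lower_is_similar = TRUE),
    ncanb  = list(input = "freqs", range = c(0, 1),
                  lower_is_similar = TRUE),
    bc     = list(input = "counts", range = c(0, 1),
                  lower_is_similar = TRUE),
    ngd    = list(input = "counts", range = c(0, 1),
                  lower_is_similar = TRUE),
    d2star = list(input = "counts+background", range = c(0, 1),
                  lower_is_similar = TRUE),
    d2s    = list(input = "counts+background", range = c(0, 1),
                  lower_is_similar = TRUE))
  c(list(name = name), info)
}

#' Names of all available metrics
#'
#' @return Character vector of metric acronyms.
#' @export
metric_names <- function() {
  c("d2raw", "d2", "euclid", "manh", "cheby", "ncanb", "bc", "ngd",
    "d2star", "d2s")
}

# align two sparse named vectors onto the union of their supports
align_sparse <- function(a, b) {
  words <- union(names(a), names(b))
  x <- numeric(length(words)); names(x) <- words
  y <- x
  x[names(a)] <- a
  y[names(b)] <- b
  list(x = x, y = y)
}

check_same_spec <- function(cr, cq) {
  if (cr$spec$alphabet$name != cq$spec$alphabet$name ||
      cr$spec$k != cq$spec$k ||
      !identical(cr$spec$masks, cq$spec$masks))
    stop("k-mer specs of the two vectors do not match")
}

#' Raw D2 statistic
#'
#' \eqn{D2(r,q) = \sum_w C_r(w)\,C_q(w)}: the inner product of the two
#' k-mer count vectors over the shared word space. Higher = more similar;
#' the value scales with sequence length.
#'
#' @param cr,cq \code{\link{kmer_counts}} with identical specs.
#' @return Non-negative numeric scalar.
#' @export
d2_raw <- function(cr, cq) {
  check_same_spec(cr, cq)
  shared <- intersect(names(cr$counts), names(cq$counts))
  sum(as.numeric(cr$counts[shared]) * as.numeric(cq$counts[shared]))
}

#' Cosine similarity of count vectors
#'
#' \eqn{D2 / (\|C_r\|\,\|C_q\|)}; 1 for parallel vectors, 0 for disjoint
#' word sets. With non-negative counts the value lies in [0, 1].
#'
#' @inheritParams d2_raw
#' @return Numeric in [0, 1].
#' @export
cosine_similarity <- function(cr, cq) {
  check_same_spec(cr, cq)
  if (cr$total == 0L || cq$total == 0L)
    stop("cosine undefined for an empty count vector")
  d2_raw(cr, cq) /
    (sqrt(sum(as.numeric(cr$counts)^2)) *
     sqrt(sum(as.numeric(cq$counts)^2)))
}

#' d2 distance (cosine mapped onto a distance)
#'
#' \eqn{0.5\,(1 - \cos)}, the standard map of a cosine in [-1, 1] onto
#' [0, 1]; since k-mer counts are non-negative the realised range is
#' [0, 0.5], with 0 for identically-directed vectors.
#'
#' @inheritParams d2_raw
#' @return Numeric in [0, 0.5].
#' @export
d2_distance <- function(cr, cq)
  min(1, max(0, 0.5 * (1 - cosine_similarity(cr, cq))))

#' Minkowski-family distances on frequency vectors
#'
#' Euclidean \eqn{\sqrt{\sum (x-y)^2}}, Manhattan \eqn{\sum |x-y|} and
#' Chebyshev \eqn{\max |x-y|} over the full word space (absent words count
#' as frequency 0). On the frequency simplex the ranges are [0, sqrt(2)],
#' [0, 2] and [0, 1] respectively.
#'
#' @param fr,fq \code{\link{kmer_freqs}} with identical specs.
#' @param which One of \code{"euclid"}, \code{"manh"}, \code{"cheby"}.
#' @return Non-negative numeric scalar.
#' @export
minkowski_family <- function(fr, fq, which = c("euclid", "manh", "cheby")) {
  which <- match.arg(which)
  check_same_spec(fr, fq)
  al <- align_sparse(fr$freqs, fq$freqs)
  d <- abs(al$x - al$y)
  switch(which,
         euclid = sqrt(sum(d^2)),
         manh   = sum(d),
         cheby  = if (length(d)) max(d) else 0)
}

#' Normalised Canberra distance
#'
#' \eqn{\frac{1}{D} \sum_{w: x_w + y_w > 0} \frac{|x_w - y_w|}{x_w + y_w}},
#' where \eqn{D} is the number of words with non-zero denominator; the
#' normalisation puts the score in [0, 1] (1 = disjoint supports).
#'
#' @inheritParams minkowski_family
#' @return Numeric in [0, 1].
#' @export
normalised_canberra <- function(fr, fq) {
  check_same_spec(fr, fq)
  al <- align_sparse(fr$freqs, fq$freqs)
  s <- al$x + al$y
  keep <- s > 0
  if (!any(keep)) stop("both frequency vectors are all-zero")
  sum(abs(al$x[keep] - al$y[keep]) / s[keep]) / sum(keep)
}

# shared-word mass of Bray-Curtis / NGD
shared_count <- function(cr, cq) {
  shared <- intersect(names(cr$counts), names(cq$counts))
  sum(pmin(as.numeric(cr$counts[shared]), as.numeric(cq$counts[shared])))
}

#' Bray-Curtis dissimilarity on count vectors
#'
#' \eqn{1 - 2C_{ij}/(S_i + S_j)} where \eqn{C_{ij} = \sum_w
#' \min(C_r(w), C_q(w))} is the k-mer mass common to both sequences and
#' \eqn{S} are the total counts. Borrowed from ecology (sites = sequences,
#' species = k-mers); assumes the two sequences are of comparable size.
#'
#' @inheritParams d2_raw
#' @return Numeric in [0, 1].
#' @export
bray_curtis <- function(cr, cq) {
  check_same_spec(cr, cq)
  s <- cr$total + cq$total
  if (s == 0L) stop("both count vectors are empty")
  1 - 2 * shared_count(cr, cq) / s
}

#' Normalised Google Distance on count vectors
#'
#' \eqn{(\max(S_i,S_j) - C_{ij}) / ((S_i + S_j) - \min(S_i,S_j))} with
#' \eqn{C_{ij}} as in \code{\link{bray_curtis}}. Note the bound
#' \eqn{NGD \ge (S_{long} - S_{short}) / S_{long}}: very unequal sequence
#' lengths force the score towards 1 regardless of content.
#'
#' @inheritParams d2_raw
#' @return Numeric in [0, 1].
#' @export
ngd <- function(cr, cq) {
  check_same_spec(cr, cq)
  smax <- max(cr$total, cq$total)
  smin <- min(cr$total, cq$total)
  if (smax == 0L) stop("both count vectors are empty")
  (smax - shared_count(cr, cq)) / ((cr$total + cq$total) - smin)
}

d2star_parts <- function(cr, br, cq, bq) {
  if (cr$spec$alphabet$name != "dna")
    stop("d2star/d2s require DNA input (no protein background)")
  check_same_spec(cr, cq)
  if (cr$total == 0L || cq$total == 0L)
    stop("d2star/d2s undefined for an empty count vector")
  ccr <- centered_counts(cr, br)
  ccq <- centered_counts(cq, bq)
  bad <- (ccr$probs == 0 & ccr$raw > 0) | (ccq$probs == 0 & ccq$raw > 0)
  if (any(bad))
    stop("word observed but has zero background probability: ",
         paste(utils::head(ccr$words[bad], 3), collapse = ", "))
  keep <- ccr$probs > 0 & ccq$probs > 0
  list(xt = ccr$centered[keep], yt = ccq$centered[keep],
       pr = ccr$probs[keep], pq = ccq$probs[keep],
       nr = cr$total, nq = cq$total)
}

#' d2Star distance
#'
#' Background-corrected D2: with \eqn{\tilde X_w = C_r(w) - n_r p^r_w} and
#' \eqn{\tilde Y_w = C_q(w) - n_q p^q_w} (order-0 Markov backgrounds fitted
#' per sequence),
#' \deqn{D2^* = \sum_w \frac{\tilde X_w \tilde Y_w}
#'   {\sqrt{n_r n_q}\sqrt{p^r_w p^q_w}}}
#' normalised by the norms of \eqn{\tilde X_w/\sqrt{n_r p^r_w}} and
#' \eqn{\tilde Y_w/\sqrt{n_q p^q_w}}, then mapped to a distance
#' \eqn{0.5 (1 - \rho)}. Unrelated sequences score near 0.5; identical
#' sequences score 0.
#'
#' @param cr,cq DNA \code{\link{kmer_counts}}.
#' @param br,bq \code{\link{markov_background}}s fitted to the same
#'   sequences (see \code{\link{fit_background}}).
#' @return Numeric in [0, 1].
#' @export
d2star <- function(cr, br, cq, bq) {
  p <- d2star_parts(cr, br, cq, bq)
  num <- sum(p$xt * p$yt / (sqrt(p$nr * p$nq) * sqrt(p$pr * p$pq)))
  nx <- sqrt(sum(p$xt^2 / (p$nr * p$pr)))
  ny <- sqrt(sum(p$yt^2 / (p$nq * p$pq)))
  if (nx == 0 || ny == 0)
    stop("degenerate centered vector (all words at expectation)")
  min(1, max(0, 0.5 * (1 - num / (nx * ny))))
}

#' d2S (d2Shepp) distance
#'
#' Background-corrected D2 with per-word self-normalisation: with
#' \eqn{\tilde X_w, \tilde Y_w} as in \code{\link{d2star}},
#' \deqn{D2S = \sum_w \frac{\tilde X_w \tilde Y_w}
#'   {\sqrt{\tilde X_w^2 + \tilde Y_w^2}}}
#' normalised by \eqn{\sqrt{\sum \tilde X_w^2/\sqrt{\tilde X_w^2+\tilde
#' Y_w^2}}\cdot\sqrt{\sum \tilde Y_w^2/\sqrt{\tilde X_w^2+\tilde Y_w^2}}},
#' then mapped to \eqn{0.5 (1 - \rho)}. Words with
#' \eqn{\tilde X_w = \tilde Y_w = 0} are skipped.
#'
#' @inheritParams d2star
#' @return Numeric in [0, 1].
#' @export
d2s <- function(cr, br, cq, bq) {
  p <- d2star_parts(cr, br, cq, bq)
  denom <- sqrt(p$xt^2 + p$yt^2)
  keep <- denom > 0
  if (!any(keep))
    stop("degenerate centered vectors (all words at expectation)")
  xt <- p$xt[keep]; yt <- p$yt[keep]; denom <- denom[keep]
  num <- sum(xt * yt / denom)
  nx <- sqrt(sum(xt^2 / denom))
  ny <- sqrt(sum(yt^2 / denom))
  min(1, max(0, 0.5 * (1 - num / (nx * ny))))
}

#' Score one sequence pair with a named metric
#'
#' Dispatcher used by the search engine: computes whatever derived vectors
#' the metric needs (counts, frequencies, Markov background) and returns
#' the score. For repeated scoring against the same reference set use
#' \code{\link{compare_sets}}, which caches reference vectors.
#'
#' @param rec_a,rec_b \code{\link{seq_record}}s over the spec's alphabet.
#' @param spec A \code{\link{kmer_spec}}.
#' @param metric Metric acronym (see \code{\link{metric_info}}).
#' @return Numeric score.
#' @examples
#' s <- kmer_spec("dna", 2)
#' a <- seq_record("a", "ACGTACGT", "dna")
#' score_pair(a, a, s, "d2")  # 0
#' @export
score_pair <- function(rec_a, rec_b, spec, metric) {
  info <- metric_info(metric)
  ca <- count_kmers(rec_a, spec)
  cb <- count_kmers(rec_b, spec)
  switch(info$input,
    counts = switch(info$name,
      d2raw = d2_raw(ca, cb),
      d2    = d2_distance(ca, cb),
      bc    = bray_curtis(ca, cb),
      ngd   = ngd(ca, cb)),
    freqs = {
      fa <- to_frequencies(ca); fb <- to_frequencies(cb)
      if (info$name == "ncanb") normalised_canberra(fa, fb)
      else minkowski_family(fa, fb, info$name)
    },
    `counts+background` = {
      ba <- fit_background(rec_a); bb <- fit_background(rec_b)
      if (info$name == "d2star") d2star(ca, ba, cb, bb)
      else d2s(ca, ba, cb, bb)
    })
}
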