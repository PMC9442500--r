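#' Length-ratio filter
#'
#' A sequence pair passes the filter when the shorter sequence has at least
#' fraction \code{fp} of the length of the longer one, e.g. \code{fp =
#' 0.75} keeps pairs whose lengths are within 75\% of each other. Metrics
#' such as Manhattan, D2 and Euclidean benefit substantially from this
#' constraint because their scores correlate with sequence length.
#'
#' @param len_a,len_b Positive sequence lengths (vectorised).
#' @param fp Ratio threshold in (0, 1].
#' @return Logical vector.
#' @examples
#' length_filter_pass(80, 100, 0.75)  # TRUE  (ratio 0.8)
#' length_filter_pass(70, 100, 0.75)  # FALSE
#' @export
length_filter_pass <- function(len_a, len_b, fp) {
  if (any(len_a <= 0) || any(len_b <= 0))
    stop("sequence lengths must be positive")
  if (fp <= 0 || fp > 1) stop("fp must lie in (0, 1]")
  pmin(len_a, len_b) / pmax(len_a, len_b) >= fp
}

# precompute whatever derived vectors a metric needs, once per record
prepare_vectors <- function(records, spec, info) {
  lapply(records, function(r) {
    cv <- count_kmers(r, spec)
    out <- list(counts = cv, length = r$length)
    if (info$input == "freqs") out$freqs <- to_frequencies(cv)
    if (info$input == "counts+background") out$bg <- fit_background(r)
    out
  })
}

score_prepared <- function(a, b, info) {
  switch(info$input,
    counts = switch(info$name,
      d2raw = d2_raw(a$counts, b$counts),
      d2    = d2_distance(a$counts, b$counts),
      bc    = bray_curtis(a$counts, b$counts),
      ngd   = ngd(a$counts, b$counts)),
    freqs = if (info$name == "ncanb")
        normalised_canberra(a$freqs, b$freqs)
      else minkowski_family(a$freqs, b$freqs, info$name),
    `counts+background` =
      if (info$name == "d2star") d2star(a$counts, a$bg, b$counts, b$bg)
      else d2s(a$counts, a$bg, b$counts, b$bg))
}

#' Compare a query set against a reference set
#'
#' The all-pairs scoring engine. Every query is scored against every
#' reference that passes the optional length-ratio filter; per query the
#' scores are sorted ascending (rank 1 = most similar), ties broken by
#' reference input order, the optional cut-off (retain score <= cutoff)
#' applied, and the list truncated to \code{top_n}. Reference vectors are
#' computed once and reused across queries.
#'
#' With \code{dry_run = TRUE} no scoring happens: the function returns the
#' pair bookkeeping only (how many pairs would be scored after the length
#' filter), which is the cheap way to audit comparison counts for large
#' designs.
#'
#' @param queries,references Lists of \code{\link{seq_record}}s.
#' @param spec A \code{\link{kmer_spec}}.
#' @param metric Metric acronym (see \code{\link{metric_info}}).
#' @param top_n Per-query truncation; 0 keeps all retained records.
#' @param fp Optional length-ratio threshold in (0, 1] (\code{NULL} = no
#'   filter).
#' @param cutoff Optional score cut-off; records with score above it are
#'   dropped before truncation.
#' @param dry_run Count pairs without scoring.
#' @return A data frame of class \code{score_records} with columns
#'   \code{query_id}, \code{ref_id}, \code{score}, \code{rank}, grouped by
#'   query in input order, carrying attributes \code{metric},
#'   \code{n_total}, \code{n_length_filtered}, \code{n_cutoff_filtered},
#'   \code{n_truncated}, \code{n_retained} (which always sum to
#'   \code{n_total}). For \code{dry_run} a list with the counting fields
#'   only.
#' @examples
#' s <- kmer_spec("dna", 2)
#' q <- list(seq_record("q", "ACGTACGT", "dna"))
#' r <- list(seq_record("r1", "ACGTACGT", "dna"),
#'           seq_record("r2", "GGGGCCCC", "dna"))
#' compare_sets(q, r, s, "ngd")
#' @export
compare_sets <- function(queries, references, spec, metric,
                         top_n = 0L, fp = NULL, cutoff = NULL,
                         dry_run = FALSE) {
  if (length(queries) == 0L) stop("empty query set")
  if (length(references) == 0L) stop("empty reference set")
  info <- metric_info(metric)
  q_len <- vapply(queries, function(r) r$length, 0L)
  r_len <- vapply(references, function(r) r$length, 0L)
  n_total <- length(queries) * length(references)

  if (dry_run) {
    n_pass <- if (is.null(fp)) n_total else
      sum(vapply(q_len,
                 function(l) sum(length_filter_pass(l, r_len, fp)), 0L))
    return(list(n_total = n_total,
                n_length_filtered = as.integer(n_total - n_pass),
                n_scored = as.integer(n_pass)))
  }

  q_vec <- prepare_vectors(queries, spec, info)
  r_vec <- prepare_vectors(references, spec, info)
  q_ids <- unname(vapply(queries, function(r) r$id, ""))
  r_ids <- unname(vapply(references, function(r) r$id, ""))

  n_len_filt <- 0L; n_cut_filt <- 0L; n_trunc <- 0L
  per_query <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    keep <- if (is.null(fp)) rep(TRUE, length(references))
            else length_filter_pass(q_len[i], r_len, fp)
    n_len_filt <- n_len_filt + sum(!keep)
    idx <- which(keep)
    if (length(idx) == 0L) { per_query[[i]] <- NULL; next }
    sc <- vapply(idx, function(j)
      score_prepared(q_vec[[i]], r_vec[[j]], info), 0)
    ord <- order(sc, idx)      # ties broken by reference input order
    sc <- sc[ord]; idx <- idx[ord]
    if (!is.null(cutoff)) {
      drop <- sc > cutoff
      n_cut_filt <- n_cut_filt + sum(drop)
      sc <- sc[!drop]; idx <- idx[!drop]
    }
    if (top_n > 0L && length(sc) > top_n) {
      n_trunc <- n_trunc + (length(sc) - top_n)
      sc <- sc[seq_len(top_n)]; idx <- idx[seq_len(top_n)]
    }
    if (length(sc) == 0L) { per_query[[i]] <- NULL; next }
    per_query[[i]] <- data.frame(query_id = q_ids[i],
                                 ref_id = r_ids[idx],
                                 score = sc,
                                 rank = seq_along(sc),
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, per_query)
  if (is.null(out))
    out <- data.frame(query_id = character(0), ref_id = character(0),
                      score = numeric(0), rank = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("score_records", "data.frame"),
            metric = info$name,
            n_total = n_total,
            n_length_filtered = n_len_filt,
            n_cutoff_filtered = n_cut_filt,
            n_truncated = n_trunc,
            n_retained = nrow(out))
}

#' All-vs-all comparison of one sequence set
#'
#' Scores every ordered pair within one collection (self-comparisons
#' included, scoring 0 for all distance metrics) and returns the symmetric
#' square distance matrix, suitable for writing in PHYLIP style for
#' phylogeny applications.
#'
#' @param records List of \code{\link{seq_record}}s.
#' @inheritParams compare_sets
#' @return Numeric matrix with sequence ids as dimnames.
#' @export
pairwise_matrix <- function(records, spec, metric) {
  info <- metric_info(metric)
  vecs <- prepare_vectors(records, spec, info)
  ids <- vapply(records, function(r) r$id, "")
  n <- length(records)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) { m[i, j] <- m[j, i]; next }
      m[i, j] <- score_prepared(vecs[[i]], vecs[[j]], info)
    }
  }
  m
}

#' Score interleaved sequence pairs
#'
#' Records \code{2i-1} and \code{2i} of the input are compared to each
#' other and nothing else; by building such files externally the user
#' controls exactly which pairs are scored (e.g. known ortholog pairs for a
#' positive-only score distribution).
#'
#' @param records List of \code{\link{seq_record}}s of even length, or a
#'   file path readable by \code{\link{read_sequences}}.
#' @inheritParams compare_sets
#' @param alphabet Used only when \code{records} is a path.
#' @return \code{score_records} data frame, one row per pair, in input
#'   order, all ranks 1.
#' @export
interleaved_compare <- function(records, spec, metric, alphabet = NULL) {
  if (is.character(records))
    records <- read_sequences(records,
      if (is.null(alphabet)) spec$alphabet else alphabet)
  if (length(records) %% 2L != 0L)
    stop("interleaved mode requires an even number of records, got ",
         length(records))
  info <- metric_info(metric)
  n_pairs <- length(records) %/% 2L
  if (n_pairs == 0L)
    return(structure(data.frame(query_id = character(0),
                                ref_id = character(0),
                                score = numeric(0), rank = integer(0)),
                     class = c("score_records", "data.frame"),
                     metric = info$name))
  vecs <- prepare_vectors(records, spec, info)
  ids <- unname(vapply(records, function(r) r$id, ""))
  i <- 2L * seq_len(n_pairs) - 1L
  sc <- vapply(seq_len(n_pairs), function(p)
    score_prepared(vecs[[2L * p - 1L]], vecs[[2L * p]], info), 0)
  structure(data.frame(query_id = ids[i], ref_id = ids[i + 1L],
                       score = sc, rank = 1L, stringsAsFactors = FALSE),
            class = c("score_records", "data.frame"),
            metric = info$name)
}

#' Keep only each query's best hit
#'
#' @param records A \code{score_records} data frame.
#' @return The rank-1 rows, one per query, in first-appearance order.
#' @export
top_hits <- function(records) {
  out <- records[records$rank == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write search results
#'
#' \code{blastlike} writes a tab-separated table (\code{query_id},
#' \code{ref_id}, \code{score}, \code{rank}) with a header row;
#' \code{matrix} writes a square symmetric distance matrix (from
#' \code{\link{pairwise_matrix}}) in PHYLIP style: the sequence count on
#' the first line, then one id and its row per line.
#'
#' @param x A \code{score_records} data frame (\code{blastlike}) or square
#'   matrix (\code{matrix}).
#' @param path Output file.
#' @param format \code{"blastlike"} or \code{"matrix"}.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path, format = c("blastlike", "matrix")) {
  format <- match.arg(format)
  if (format == "blastlike") {
    stopifnot(is.data.frame(x))
    utils::write.table(x[, c("query_id", "ref_id", "score", "rank")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!is.matrix(x) || nrow(x) != ncol(x))
      stop("matrix output requires a square all-vs-all matrix")
    if (max(abs(x - t(x))) > 1e-12)
      stop("matrix output requires a symmetric result set")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(x)), con)
    for (i in seq_len(nrow(x)))
      writeLines(paste(c(rownames(x)[i],
                         formatC(x[i, ], format = "g", digits = 10)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a blastlike result table back
#'
#' @param path File written by \code{\link{write_results}}.
#' @return \code{score_records} data frame.
#' @export
read_results <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  structure(out, class = c("score_records", "data.frame"))
}
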