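#' Extract non-overlapping query and reference fragments from a genome
#'
#' Emulates a fragment-extraction protocol that avoids the bias of genomes
#' being recorded from the origin of replication: the genome is divided
#' into ~10 equal intervals (remainder bases dropped), query fragments are
#' taken from the odd-numbered intervals (1st, 3rd, ...) and reference
#' fragments from the even-numbered ones, each fragment being the first
#' \code{L} bases of its interval. Queries and references therefore never
#' overlap and sample along the whole genome. With the default 10
#' intervals this yields 5 query and 5 reference fragments per length
#' \code{L}; if \code{L} exceeds the interval width, only as many complete
#' fragments as fit are returned, with a warning.
#'
#' @param genome A DNA \code{\link{seq_record}}.
#' @param L Fragment length in bp.
#' @param n_intervals Number of intervals (default 10).
#' @return List with \code{queries} and \code{references}, each a list of
#'   \code{seq_record}s with ids \code{<genome id>_q<i>} /
#'   \code{<genome id>_r<i>}.
#' @export
make_fragments <- function(genome, L, n_intervals = 10L) {
  stopifnot(inherits(genome, "seq_record"), L >= 1L)
  width <- genome$length %/% n_intervals
  if (L > width) {
    warning("L = ", L, " exceeds the interval width ", width,
            " for genome ", genome$id, "; emitting fewer fragments")
  }
  starts <- (seq_len(n_intervals) - 1L) * width + 1L
  # fragments are anchored at interval starts; when L > width only those
  # that still fit inside the genome are emitted
  ok <- starts + L - 1L <= genome$length
  q_idx <- which(ok & (seq_len(n_intervals) %% 2L == 1L))
  r_idx <- which(ok & (seq_len(n_intervals) %% 2L == 0L))
  cut1 <- function(i, tag, num)
    seq_record(paste0(genome$id, "_", tag, num),
               substr(genome$residues, starts[i], starts[i] + L - 1L),
               genome$alphabet)
  list(queries = mapply(cut1, q_idx, "q", seq_along(q_idx),
                        SIMPLIFY = FALSE),
       references = mapply(cut1, r_idx, "r", seq_along(r_idx),
                           SIMPLIFY = FALSE))
}

#' Fixed-length reference prefix of a genome
#'
#' The unequal-length design: query fragments vary over the length sweep
#' while the reference is the genome's first \code{ref_length} bases
#' (250 kb by default), exposing how length-sensitive metrics degrade when
#' query and reference sizes differ.
#'
#' @param genome A DNA \code{\link{seq_record}}.
#' @param ref_length Prefix length in bp; truncated to the genome length.
#' @return A \code{seq_record} with id \code{<genome id>_ref}.
#' @export
make_fixed_reference <- function(genome, ref_length = 250000L) {
  stopifnot(inherits(genome, "seq_record"))
  n <- min(ref_length, genome$length)
  seq_record(paste0(genome$id, "_ref"),
             substr(genome$residues, 1L, n), genome$alphabet)
}

# order-1 Markov chain over 1..4, thresholds precomputed per state
simulate_markov_chain <- function(n, trans, init) {
  cum <- t(apply(trans, 1L, cumsum))
  t1 <- cum[, 1L]; t2 <- cum[, 2L]; t3 <- cum[, 3L]
  u <- stats::runif(n)
  x <- integer(n)
  s <- 1L + sum(u[1L] > cumsum(init)[1:3])
  x[1L] <- s
  for (i in seq_len(n - 1L) + 1L) {
    ui <- u[i]
    s <- 1L + (ui > t1[s]) + (ui > t2[s]) + (ui > t3[s])
    x[i] <- s
  }
  x
}

#' Simulate genomes with distinct compositional signatures
#'
#' Generates reproducible synthetic genomes, each produced by its own
#' order-1 Markov chain whose transition rows are drawn around a shared
#' base composition with a per-genome log-normal perturbation. The
#' perturbation strength controls how distinct the genome "signatures"
#' are: at 0 every genome is an i.i.d. sample of the shared composition
#' and no metric can tell fragments apart; at moderate strengths fragments
#' of the same genome score systematically more similar than fragments of
#' different genomes. This is an explicit synthetic stand-in for real
#' genome collections, used for directional and recovery tests.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length of each genome in bp.
#' @param perturbation Standard deviation of the per-genome log-normal
#'   perturbation of the transition rows (0 = no signal).
#' @param seed Integer seed; the same seed reproduces the genomes exactly.
#' @param base_probs Shared base composition over A, C, G, T.
#' @return List with \code{genomes} (list of \code{seq_record}s, ids
#'   \code{g01}, \code{g02}, ...), \code{taxonomy} (data frame: id,
#'   species, genus, one row per genome; species = genome id, genera pool
#'   consecutive genome pairs) and \code{manifest} (generation
#'   parameters).
#' @export
simulate_signature_genomes <- function(n_genomes, genome_length,
                                       perturbation = 0.5, seed = 1L,
                                       base_probs = c(A = 0.3, C = 0.2,
                                                      G = 0.2, T = 0.3)) {
  stopifnot(n_genomes >= 1L, genome_length >= 10L, perturbation >= 0)
  if (abs(sum(base_probs) - 1) > 1e-9)
    stop("base_probs must sum to 1")
  set.seed(seed)
  letters4 <- c("A", "C", "G", "T")
  ids <- sprintf("g%02d", seq_len(n_genomes))
  genomes <- vector("list", n_genomes)
  for (g in seq_len(n_genomes)) {
    trans <- matrix(0, 4L, 4L)
    for (row in 1:4) {
      w <- base_probs * exp(perturbation * stats::rnorm(4L))
      trans[row, ] <- w / sum(w)
    }
    init <- colSums(trans) / 4
    x <- simulate_markov_chain(genome_length, trans, init)
    genomes[[g]] <- seq_record(ids[g],
                               paste(letters4[x], collapse = ""), "dna")
  }
  names(genomes) <- ids
  taxonomy <- data.frame(id = ids, species = ids,
                         genus = sprintf("genus%02d",
                                         (seq_len(n_genomes) + 1L) %/% 2L),
                         stringsAsFactors = FALSE)
  list(genomes = genomes, taxonomy = taxonomy,
       manifest = list(n_genomes = n_genomes,
                       genome_length = genome_length,
                       perturbation = perturbation, seed = seed,
                       base_probs = base_probs))
}

#' Fragment benchmark from simulated genomes
#'
#' Applies \code{\link{make_fragments}} to every simulated genome and
#' assembles the query set, the reference set, and a taxonomy truth table
#' covering every fragment id (species = source genome, genus inherited
#' from the genome table), ready for \code{\link{compare_sets}} and
#' \code{\link{top_hit_accuracy}}.
#'
#' @param sim Result of \code{\link{simulate_signature_genomes}}.
#' @param L Fragment length in bp.
#' @param fixed_reference If \code{TRUE} use one
#'   \code{\link{make_fixed_reference}} prefix per genome as the reference
#'   set (unequal-length design) instead of equal-length fragments.
#' @param ref_length Prefix length for the unequal-length design.
#' @return List with \code{queries}, \code{references} (lists of
#'   \code{seq_record}s) and \code{truth} (a species-rank
#'   \code{\link{truth_taxonomy}}).
#' @export
fragment_benchmark <- function(sim, L, fixed_reference = FALSE,
                               ref_length = 250000L) {
  queries <- list(); references <- list()
  tax_rows <- list()
  for (g in sim$genomes) {
    fr <- make_fragments(g, L)
    queries <- c(queries, fr$queries)
    refs <- if (fixed_reference) list(make_fixed_reference(g, ref_length))
            else fr$references
    references <- c(references, refs)
    ids <- c(vapply(fr$queries, function(r) r$id, ""),
             vapply(refs, function(r) r$id, ""))
    row <- sim$taxonomy[sim$taxonomy$id == g$id, ]
    tax_rows[[g$id]] <- data.frame(id = ids, species = row$species,
                                   genus = row$genus,
                                   stringsAsFactors = FALSE)
  }
  truth <- truth_taxonomy(do.call(rbind, c(tax_rows,
                                           make.row.names = FALSE)),
                          rank = "species")
  list(queries = queries, references = references, truth = truth)
}

aa_background <- function() {
  # rough natural amino-acid abundances (order matches alphabet("aa"))
  p <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
         I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 4.0,
         R = 5.5, S = 6.6, T = 5.3, V = 6.9, W = 1.1, Y = 2.9)
  p / sum(p)
}

mutate_protein <- function(chars, substitution_rate, indel_rate,
                           symbols) {
  n <- length(chars)
  sub <- stats::runif(n) < substitution_rate
  if (any(sub)) {
    repl <- sample(symbols, sum(sub), replace = TRUE)
    same <- repl == chars[sub]
    while (any(same)) {
      repl[same] <- sample(symbols, sum(same), replace = TRUE)
      same <- repl == chars[sub]
    }
    chars[sub] <- repl
  }
  if (indel_rate > 0) {
    events <- which(stats::runif(n) < indel_rate)
    for (pos in rev(events)) {       # right-to-left keeps positions valid
      len <- stats::rgeom(1L, 0.5) + 1L
      if (stats::runif(1L) < 0.5) {  # deletion
        chars <- chars[-(pos:min(pos + len - 1L, length(chars)))]
      } else {                       # insertion
        ins <- sample(symbols, len, replace = TRUE,
                      prob = aa_background())
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  chars
}

#' Simulate protein ortholog pairs with decoys
#'
#' A synthetic stand-in for curated ortholog benchmarks: each true pair is
#' an ancestor protein plus a mutated copy (i.i.d. substitutions to a
#' random different residue at \code{substitution_rate}, plus
#' geometric-length indels at \code{indel_rate} per site); unrelated decoy
#' proteins are added to the reference side. Ancestor residues are drawn
#' from natural amino-acid abundances; lengths are gamma-distributed with
#' the given mean (clamped to at least 30 residues) unless an explicit
#' length vector is supplied.
#'
#' @param n_pairs Number of true ortholog pairs.
#' @param substitution_rate Per-residue substitution probability in [0, 1).
#' @param indel_rate Per-residue indel event probability in [0, 1).
#' @param n_decoys Unrelated reference-side proteins.
#' @param mean_length Mean ancestor length (gamma, shape 2.5).
#' @param lengths Optional explicit ancestor lengths (overrides
#'   \code{mean_length}).
#' @param seed Integer seed for reproducibility.
#' @return List with \code{queries} (ancestors, ids \code{q0001}, ...),
#'   \code{references} (mutated copies \code{r0001}, ... plus decoys
#'   \code{d0001}, ...), \code{pairs} (data frame of true pairs, a valid
#'   input to \code{\link{truth_pairs}}) and \code{manifest}.
#' @export
simulate_ortholog_proteins <- function(n_pairs,
                                       substitution_rate = 0.3,
                                       indel_rate = 0.01,
                                       n_decoys = n_pairs,
                                       mean_length = 450,
                                       lengths = NULL, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1)
    stop("mutation rates must lie in [0, 1)")
  set.seed(seed)
  symbols <- alphabet("aa")$symbols
  bg <- aa_background()
  if (is.null(lengths))
    lengths <- pmax(30L, round(stats::rgamma(n_pairs, shape = 2.5,
                                             scale = mean_length / 2.5)))
  stopifnot(length(lengths) == n_pairs)
  queries <- vector("list", n_pairs)
  refs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- sample(symbols, lengths[i], replace = TRUE, prob = bg)
    mut <- mutate_protein(anc, substitution_rate, indel_rate, symbols)
    if (length(mut) == 0L) mut <- sample(symbols, 1L, prob = bg)
    queries[[i]] <- seq_record(sprintf("q%04d", i),
                               paste(anc, collapse = ""), "aa")
    refs[[i]] <- seq_record(sprintf("r%04d", i),
                            paste(mut, collapse = ""), "aa")
  }
  decoys <- vector("list", n_decoys)
  if (n_decoys > 0L) {
    dec_len <- pmax(30L, round(stats::rgamma(n_decoys, shape = 2.5,
                                             scale = mean_length / 2.5)))
    for (i in seq_len(n_decoys))
      decoys[[i]] <- seq_record(sprintf("d%04d", i),
                                paste(sample(symbols, dec_len[i],
                                             replace = TRUE, prob = bg),
                                      collapse = ""), "aa")
  }
  references <- c(refs, decoys)
  names(queries) <- vapply(queries, function(r) r$id, "")
  names(references) <- vapply(references, function(r) r$id, "")
  pairs <- data.frame(id_a = names(queries),
                      id_b = vapply(refs, function(r) r$id, ""),
                      stringsAsFactors = FALSE)
  list(queries = queries, references = references, pairs = pairs,
       manifest = list(n_pairs = n_pairs,
                       substitution_rate = substitution_rate,
                       indel_rate = indel_rate, n_decoys = n_decoys,
                       mean_length = mean_length, seed = seed))
}

#' Interleave true pairs into one record list
#'
#' Arranges the true pairs of a simulated ortholog set as an interleaved
#' collection (query, partner, query, partner, ...) for
#' \code{\link{interleaved_compare}} or \code{\link{write_fasta}}.
#'
#' @param sim Result of \code{\link{simulate_ortholog_proteins}}.
#' @return List of \code{seq_record}s of even length.
#' @export
interleave_pairs <- function(sim) {
  out <- vector("list", 2L * nrow(sim$pairs))
  for (i in seq_len(nrow(sim$pairs))) {
    out[[2L * i - 1L]] <- sim$queries[[sim$pairs$id_a[i]]]
    out[[2L * i]] <- sim$references[[sim$pairs$id_b[i]]]
  }
  out
}
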