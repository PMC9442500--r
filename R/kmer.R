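#' k-mer specification
#'
#' Defines the word space in which sequences are compared: an alphabet, a
#' word length \code{k}, and optionally one or more binary masks describing
#' spaced k-mers. A mask is a string of \code{k} characters over
#' \code{"0"}/\code{"1"}: the window slides over the sequence as usual, but
#' only positions marked \code{"1"} contribute letters to the emitted word.
#' Several masks may be used simultaneously; they must select the same
#' number of positions so their words share one word space.
#'
#' @param alphabet An \code{\link{alphabet}} or its name.
#' @param k Word length (window width), integer \eqn{\ge} 1.
#' @param masks Character vector of binary mask strings of length \code{k},
#'   or \code{NULL} for contiguous k-mers.
#' @return Object of class \code{kmer_spec}.
#' @examples
#' kmer_spec("dna", 4)
#' kmer_spec("dna", 7, masks = c("1010101", "1101100"))
#' @export
kmer_spec <- function(alphabet, k, masks = NULL) {
  alphabet <- alphabet(alphabet)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  if (!is.null(masks)) {
    masks <- as.character(masks)
    if (any(nchar(masks) != k))
      stop("each mask must have length k = ", k)
    if (any(grepl("[^01]", masks)))
      stop("masks may only contain '0' and '1'")
    ones <- vapply(masks, function(m)
      sum(strsplit(m, "")[[1]] == "1"), 0L)
    if (any(ones == 0L)) stop("each mask needs at least one '1'")
    if (length(unique(ones)) > 1L)
      stop("all masks must select the same number of positions ",
           "(shared word space)")
  }
  structure(list(alphabet = alphabet, k = k, masks = masks),
            class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat("<kmer_spec> ", x$alphabet$name, " k=", x$k, sep = "")
  if (!is.null(x$masks))
    cat(" masks=[", paste(x$masks, collapse = ","), "]", sep = "")
  cat(" (word space ", format(word_space_size(x), big.mark = ","),
      ")\n", sep = "")
  invisible(x)
}

# number of letters each emitted word carries
effective_width <- function(spec) {
  if (is.null(spec$masks)) spec$k
  else sum(strsplit(spec$masks[1], "")[[1]] == "1")
}

#' Size of the word space
#'
#' \eqn{|A|^k} for contiguous k-mers (e.g. \eqn{4^4 = 256} DNA 4-mers,
#' \eqn{20^4 = 160000} protein 4-mers), or \eqn{|A|^m} where \eqn{m} is the
#' number of \code{'1'} positions for masked specs.
#'
#' @param spec A \code{\link{kmer_spec}}.
#' @return Numeric scalar (may exceed integer range for protein k-mers).
#' @examples
#' word_space_size(kmer_spec("dna", 4))   # 256
#' word_space_size(kmer_spec("aa", 4))    # 160000
#' @export
word_space_size <- function(spec) {
  stopifnot(inherits(spec, "kmer_spec"))
  length(spec$alphabet$symbols)^effective_width(spec)
}

#' Enumerate the word space
#'
#' All possible words of a spec in lexicographic order of the alphabet's
#' canonical symbol order. Intended for dense (DNA-sized) word spaces;
#' refuses spaces above \code{max_size}.
#'
#' @param spec A \code{\link{kmer_spec}}.
#' @param max_size Guard against enumerating astronomically large protein
#'   word spaces.
#' @return Character vector of length \code{word_space_size(spec)}.
#' @export
enumerate_words <- function(spec, max_size = 1e6) {
  n <- word_space_size(spec)
  if (n > max_size)
    stop("word space too large to enumerate (", n, " words)")
  width <- effective_width(spec)
  grids <- rep(list(spec$alphabet$symbols), width)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  g <- expand.grid(rev(grids), stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(g)))
}

#' Count k-mers in a sequence
#'
#' Slides one window per start position (1 .. length - k + 1) per mask over
#' the record. Windows covering an ambiguity symbol are skipped entirely;
#' masked-out positions are deleted from the emitted word. With multiple
#' masks all words accumulate into one shared word space. A sequence
#' shorter than \code{k} yields an empty count vector (total 0), not an
#' error. Counts are stored sparsely: only observed words are kept, which
#' matters for protein word spaces where the vast majority of possible
#' k-mers never occur.
#'
#' @param record A \code{\link{seq_record}} whose alphabet matches the spec.
#' @param spec A \code{\link{kmer_spec}}.
#' @return Object of class \code{kmer_counts}: list with \code{spec},
#'   \code{counts} (named integer vector over observed words, sorted) and
#'   \code{total} (sum of counts).
#' @examples
#' r <- seq_record("x", "ACGTACGT", "dna")
#' count_kmers(r, kmer_spec("dna", 2))$counts
#' @export
count_kmers <- function(record, spec) {
  stopifnot(inherits(record, "seq_record"), inherits(spec, "kmer_spec"))
  if (record$alphabet$name != spec$alphabet$name)
    stop("record alphabet '", record$alphabet$name,
         "' does not match spec alphabet '", spec$alphabet$name, "'")
  k <- spec$k
  n <- record$length
  if (n < k)
    return(structure(list(spec = spec,
                          counts = structure(integer(0), names = character(0)),
                          total = 0L),
                     class = "kmer_counts"))
  chars <- strsplit(record$residues, "")[[1]]
  amb <- chars %in% spec$alphabet$ambiguity
  starts <- seq_len(n - k + 1L)
  # window i is clean iff no ambiguity symbol in positions i..i+k-1
  ca <- c(0L, cumsum(amb))
  clean <- (ca[starts + k] - ca[starts]) == 0L
  masks <- if (is.null(spec$masks)) strrep("1", k) else spec$masks
  words <- character(0)
  for (m in masks) {
    pos <- which(strsplit(m, "")[[1]] == "1")
    idx <- outer(starts - 1L, pos, `+`)
    cols <- lapply(seq_along(pos), function(j) chars[idx[, j]])
    w <- do.call(paste0, cols)
    words <- c(words, w[clean])
  }
  tab <- table(words)
  counts <- structure(as.integer(tab), names = as.character(names(tab)))
  structure(list(spec = spec, counts = counts,
                 total = sum(counts)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> ", length(x$counts), " distinct words, total ",
      x$total, " (", x$spec$alphabet$name, " k=", x$spec$k, ")\n", sep = "")
  invisible(x)
}

#' Convert counts to frequencies
#'
#' Divides each count by the realised total number of counted windows, so
#' that frequencies always sum to 1 even when ambiguous windows were
#' skipped. (The number of windows is length - k + 1 per mask when no
#' window is skipped.) A zero-total count vector yields an all-zero
#' frequency vector.
#'
#' @param counts A \code{\link{kmer_counts}}.
#' @return Object of class \code{kmer_freqs}: list with \code{spec},
#'   \code{freqs} (named numeric, sums to 1 when total > 0) and
#'   \code{total_kmers}.
#' @export
to_frequencies <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  freqs <- if (counts$total > 0L) counts$counts / counts$total
           else structure(numeric(0), names = character(0))
  structure(list(spec = counts$spec, freqs = freqs,
                 total_kmers = counts$total),
            class = "kmer_freqs")
}

#' Order-0 Markov background of a DNA sequence
#'
#' Estimates single-letter probabilities from the record itself (ambiguity
#' symbols excluded) and derives multiplicative expected word probabilities
#' \eqn{p_w = \prod_i p(w_i)}. This is the background used by the d2Star and
#' d2S statistics; there is no meaningful analogue for proteins (short
#' sequences, 20-letter alphabet), so amino-acid input is rejected.
#'
#' @param record A DNA \code{\link{seq_record}} of positive length.
#' @return Object of class \code{markov_background} with element
#'   \code{letter_probs} (named over A, C, G, T, summing to 1).
#' @examples
#' fit_background(seq_record("x", "AAC", "dna"))$letter_probs
#' @export
fit_background <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  if (record$alphabet$name != "dna")
    stop("Markov background is only defined for DNA input")
  if (record$length == 0L) stop("cannot fit background to empty sequence")
  chars <- strsplit(record$residues, "")[[1]]
  chars <- chars[chars %in% record$alphabet$symbols]
  if (length(chars) == 0L)
    stop("sequence contains no canonical residues")
  tab <- table(factor(chars, levels = record$alphabet$symbols))
  probs <- as.numeric(tab) / sum(tab)
  names(probs) <- record$alphabet$symbols
  structure(list(letter_probs = probs), class = "markov_background")
}

#' Expected word probabilities under an order-0 background
#'
#' @param background A \code{\link{markov_background}}.
#' @param words Character vector of words.
#' @return Numeric vector of \eqn{p_w = \prod p(letter)}.
#' @export
word_probs <- function(background, words) {
  stopifnot(inherits(background, "markov_background"))
  p <- background$letter_probs
  vapply(strsplit(words, ""), function(ch) prod(p[ch]), 0)
}

#' Background-centred count vector over the full word space
#'
#' Returns \eqn{\tilde X_w = C(w) - n p_w} for every word of the spec's
#' word space, where \eqn{n} is the realised total k-mer count. The sum of
#' centred counts is 0 up to floating error.
#'
#' @param counts A \code{\link{kmer_counts}} (DNA).
#' @param background A \code{\link{markov_background}} fitted to the same
#'   sequence.
#' @return List with \code{words}, \code{probs} (\eqn{p_w}), \code{raw}
#'   (dense counts) and \code{centered} (\eqn{\tilde X_w}).
#' @export
centered_counts <- function(counts, background) {
  stopifnot(inherits(counts, "kmer_counts"))
  words <- enumerate_words(counts$spec)
  raw <- numeric(length(words))
  names(raw) <- words
  raw[names(counts$counts)] <- counts$counts
  probs <- word_probs(background, words)
  list(words = words, probs = probs, raw = raw,
       centered = raw - counts$total * probs)
}
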