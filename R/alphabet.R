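#' Sequence alphabets
#'
#' An alphabet defines the canonical residue symbols that are counted as
#' k-mers and the ambiguity symbols that are tolerated on input but never
#' counted (any k-mer window containing one is skipped). Three alphabets are
#' provided: \code{"dna"} (A, C, G, T with the IUPAC ambiguity codes
#' tolerated), \code{"aa"} (the 20 standard amino acids with X, B, Z, J, U,
#' O and \code{*} tolerated), and \code{"raa10"}, a reduced 10-letter
#' amino-acid alphabet obtained by pooling physico-chemically similar
#' residues (Murphy-style grouping: LVIM, C, A, G, ST, P, FYW, EDNQ, KR, H,
#' each written as its first member).
#'
#' @param name One of \code{"dna"}, \code{"aa"}, \code{"raa10"}, or an
#'   existing \code{alphabet} object (returned unchanged).
#' @return An object of class \code{alphabet} with elements \code{name},
#'   \code{symbols} (canonical characters, in canonical order) and
#'   \code{ambiguity} (characters tolerated but never counted).
#' @examples
#' alphabet("dna")
#' alphabet("raa10")$symbols
#' @export
alphabet <- function(name) {
  if (inherits(name, "alphabet")) return(name)
  name <- match.arg(name, c("dna", "aa", "raa10"))
  def <- switch(name,
    dna = list(
      symbols   = c("A", "C", "G", "T"),
      ambiguity = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")),
    aa = list(
      symbols   = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
      ambiguity = c("X", "B", "Z", "J", "U", "O", "*")),
    raa10 = list(
      symbols   = c("L", "C", "A", "G", "S", "P", "F", "E", "K", "H"),
      ambiguity = c("X", "B", "Z", "J", "U", "O", "*")))
  structure(list(name = name, symbols = def$symbols,
                 ambiguity = def$ambiguity),
            class = "alphabet")
}

#' @export
print.alphabet <- function(x, ...) {
  cat("<alphabet> ", x$name, ": ", paste(x$symbols, collapse = ""),
      "  (ambiguity: ", paste(x$ambiguity, collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Reduced amino-acid grouping table
#'
#' The default 10-group reduction pools {L,V,I,M}, {C}, {A}, {G}, {S,T},
#' {P}, {F,Y,W}, {E,D,N,Q}, {K,R} and {H}; each group is represented by its
#' first member. Ambiguity symbols map to \code{"X"}.
#'
#' @return Named character vector mapping each standard amino acid (and
#'   ambiguity symbol) to its group representative.
#' @export
raa10_grouping <- function() {
  groups <- c("LVIM", "C", "A", "G", "ST", "P", "FYW", "EDNQ", "KR", "H")
  map <- character(0)
  for (g in groups) {
    letters <- strsplit(g, "")[[1]]
    map[letters] <- letters[1]
  }
  amb <- alphabet("aa")$ambiguity
  map[amb] <- "X"
  map
}

#' Reduce a protein record to the 10-letter alphabet
#'
#' Rewrites each residue of an amino-acid sequence record as its group
#' representative under a reduced-alphabet grouping. Sequence length is
#' preserved; ambiguity symbols become \code{"X"}.
#'
#' @param record A \code{seq_record} over the \code{aa} alphabet.
#' @param grouping Named character map from residue to group symbol;
#'   defaults to \code{\link{raa10_grouping}}.
#' @return A \code{seq_record} over the \code{raa10} alphabet.
#' @examples
#' rec <- seq_record("p1", "LLVI", alphabet("aa"))
#' reduce_alphabet(rec)$residues  # "LLLL"
#' @export
reduce_alphabet <- function(record, grouping = raa10_grouping()) {
  stopifnot(inherits(record, "seq_record"))
  if (record$alphabet$name != "aa")
    stop("reduce_alphabet() requires an amino-acid record, got '",
         record$alphabet$name, "'")
  chars <- strsplit(record$residues, "")[[1]]
  out <- unname(grouping[chars])
  if (anyNA(out))
    stop("residues not covered by the grouping table: ",
         paste(unique(chars[is.na(out)]), collapse = ", "))
  seq_record(record$id, paste(out, collapse = ""), alphabet("raa10"),
             description = record$description)
}
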