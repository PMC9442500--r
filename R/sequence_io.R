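#' Construct a sequence record
#'
#' The atomic unit of the engine: an identifier, an optional free-text
#' description (the full FASTA header), the residue string and its declared
#' alphabet. Residues are upper-cased and validated: characters outside the
#' alphabet's canonical and ambiguity sets are an error.
#'
#' @param id Sequence identifier (first whitespace-delimited header token);
#'   must be non-empty.
#' @param residues Residue string.
#' @param alphabet An \code{\link{alphabet}} or its name.
#' @param description Full header line; defaults to \code{id}.
#' @return An object of class \code{seq_record} with elements \code{id},
#'   \code{description}, \code{residues}, \code{length}, \code{alphabet}.
#' @export
seq_record <- function(id, residues, alphabet = "dna", description = id) {
  alphabet <- alphabet(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  residues <- toupper(as.character(residues))
  chars <- strsplit(residues, "")[[1]]
  legal <- c(alphabet$symbols, alphabet$ambiguity)
  bad <- setdiff(unique(chars), legal)
  if (length(bad) > 0L)
    stop("illegal character(s) for alphabet '", alphabet$name, "' in '",
         id, "': ", paste(bad, collapse = ", "))
  structure(list(id = id, description = description, residues = residues,
                 length = nchar(residues), alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  head <- if (x$length > 50L) paste0(substr(x$residues, 1L, 50L), "...")
          else x$residues
  cat("<seq_record> ", x$id, " (", x$alphabet$name, ", ", x$length,
      " residues)\n  ", head, "\n", sep = "")
  invisible(x)
}

infer_format <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", p))
  if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
}

#' Read sequence records from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file into an ordered
#' list of \code{\link{seq_record}} objects. The format is inferred from the
#' file extension (\code{.fa}/\code{.fasta} vs \code{.fq}/\code{.fastq},
#' with an optional \code{.gz} suffix). Records are returned in file order
#' (required by interleaved-pair comparison), residues are upper-cased, and
#' any character outside the alphabet's canonical and ambiguity sets raises
#' an error. FASTQ quality strings are ignored. Parsing is delegated to
#' \pkg{Biostrings}, which handles gzip transparently.
#'
#' @param path Path to the sequence file.
#' @param alphabet Target \code{\link{alphabet}} or its name.
#' @return Named list of \code{seq_record}s (names are sequence ids),
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "ACGT", ">b", "GG"), fa)
#' recs <- read_sequences(fa, "dna")
#' vapply(recs, function(r) r$length, 0L)
#' @export
read_sequences <- function(path, alphabet = "dna") {
  alphabet <- alphabet(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- infer_format(path)
  xs <- Biostrings::readBStringSet(path, format = fmt)
  if (length(xs) == 0L) stop("no sequence records in ", path)
  headers <- names(xs)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  if (any(!nzchar(ids))) stop("record with empty identifier in ", path)
  seqs <- as.character(xs)
  out <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    out[[i]] <- seq_record(ids[i], seqs[i], alphabet,
                           description = headers[i])
  }
  names(out) <- ids
  out
}

#' Write sequence records as FASTA
#'
#' Writes records in order, one header (\code{>description}) and one
#' sequence line per record. The main use besides persistence is building
#' interleaved pair files where records \code{2i-1} and \code{2i} form a
#' comparison pair.
#'
#' @param records List of \code{\link{seq_record}}s.
#' @param path Output path (\code{.gz} suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (r in records) {
    stopifnot(inherits(r, "seq_record"))
    writeLines(c(paste0(">", r$description), r$residues), con)
  }
  invisible(path)
}

#' Flag ambiguity symbols in a record
#'
#' Positions of tolerated-but-uncounted symbols (e.g. N for DNA, X for
#' protein). K-mer windows covering any of these positions are skipped
#' during counting.
#'
#' @param record A \code{\link{seq_record}}.
#' @return Integer vector of 1-based ambiguous positions.
#' @export
ambiguous_positions <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  chars <- strsplit(record$residues, "")[[1]]
  which(chars %in% record$alphabet$ambiguity)
}
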