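#' Normalise a raw nucleotide string
#'
#' Uppercases, strips whitespace, maps RNA `U` to `T`, and replaces every
#' remaining non-`ACGT` character (IUPAC ambiguity codes and anything else)
#' with `N`.  Total on strings and idempotent.
#'
#' @param raw Character vector of raw sequence strings.
#' @return Character vector of the same length over the alphabet
#'   `{A,C,G,T,N}`.
#' @examples
#' clean_sequence("acgu")   # "ACGT"
#' clean_sequence("ACRGT")  # "ACNGT"
#' @export
clean_sequence <- function(raw) {
  x <- toupper(gsub("[ \t\r\n\v\f]", "", as.character(raw)))
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

#' Read and validate a multi-FASTA file
#'
#' Records are returned in file order as a named character vector of cleaned
#' residues (see [clean_sequence()]).  The id of a record is the first
#' whitespace-delimited token of its header line.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector; names are record ids, values are residue
#'   strings over `{A,C,G,T,N}`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with an empty id in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- clean_sequence(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("FASTA record(s) with an empty sequence body: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residues.
#' @param path Output file path.
#' @param width Line-wrap width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
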