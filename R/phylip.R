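#' Write a distance matrix in PHYLIP square format
#'
#' First line: N.  Then one row per taxon: label followed by N distances.
#' With `strict = TRUE` labels are truncated/padded to 10 characters; by
#' default the relaxed dialect is used (full labels, whitespace-separated),
#' which round-trips through [read_phylip_dist()].
#'
#' @param D Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @param strict Use strict 10-character PHYLIP labels.
#' @param digits Significant digits for distances.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path, strict = FALSE, digits = 10L) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(rownames(D)))
  labels <- rownames(D)
  if (strict) {
    labels <- formatC(substr(labels, 1L, 10L), width = -10L)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(labels[i],
                     paste(formatC(D[i, ], digits = digits, format = "g"),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path to a PHYLIP square matrix file (relaxed labels).
#' @return Symmetric numeric matrix with taxon labels as dimnames.
#' @export
read_phylip_dist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 2L) {
    stop("not a PHYLIP distance matrix: bad taxon count line", call. = FALSE)
  }
  if (length(lines) < n + 1L) {
    stop("truncated PHYLIP matrix: expected ", n, " rows", call. = FALSE)
  }
  labels <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    if (length(tok) != n + 1L) {
      stop("row ", i, " has ", length(tok) - 1L, " values, expected ", n,
           call. = FALSE)
    }
    labels[i] <- tok[1L]
    D[i, ] <- as.numeric(tok[-1L])
  }
  if (anyNA(D)) stop("non-numeric distance entries", call. = FALSE)
  dimnames(D) <- list(labels, labels)
  D
}
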