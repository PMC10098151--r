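# Base codes A=0, C=1, G=2, T=3; anything else (N) is NA so that windows
# containing it drop out of the index arithmetic.
.BASE_LUT <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut
})

# Memory cap: a dense count array of length 4^k in 32-bit integers.
.K_MAX <- 14L

.encode_bases <- function(seq) {
  .BASE_LUT[utf8ToInt(seq) + 1L]
}

.check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1L || k != as.integer(k)) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  if (k > .K_MAX) {
    stop("k = ", k, " exceeds the supported maximum of ", .K_MAX,
         " (a dense 4^k count array would be too large)", call. = FALSE)
  }
  as.integer(k)
}

#' Base-4 index of a k-mer
#'
#' Maps a word over `{A,C,G,T}` to its index in `[0, 4^k)` by reading the
#' word as a base-4 number with digits A=0, C=1, G=2, T=3 (first base most
#' significant).  The map is a bijection between N-free words of length k
#' and `0:(4^k - 1)`, so it can address a dense count array directly.
#'
#' @param word Character vector of equal-length words over `{A,C,G,T}`.
#' @return Integer vector of indices in `[0, 4^k)`.
#' @examples
#' kmer_index("AAA")   # 0
#' kmer_index("TTT")   # 63
#' kmer_index("ACGT")  # 27
#' @export
kmer_index <- function(word) {
  k <- unique(nchar(word))
  if (length(k) != 1L) stop("all words must have the same length", call. = FALSE)
  .check_k(k)
  vapply(word, function(w) {
    codes <- .encode_bases(w)
    if (anyNA(codes)) {
      stop("invalid k-mer (non-ACGT character): ", w, call. = FALSE)
    }
    idx <- 0L
    for (c in codes) idx <- idx * 4L + c
    idx
  }, integer(1), USE.NAMES = FALSE)
}

#' Reconstruct the k-mer string for an index
#'
#' Inverse of [kmer_index()].
#'
#' @param idx Integer vector of indices in `[0, 4^k)`.
#' @param k Word length.
#' @return Character vector of k-mers.
#' @export
kmer_word <- function(idx, k) {
  k <- .check_k(k)
  stopifnot(all(idx >= 0), all(idx < 4^k))
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    out <- character(k)
    for (j in k:1) {
      out[j] <- bases[i %% 4 + 1]
      i <- i %/% 4
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Count the k-mers of one sequence
#'
#' Produces the k-mer spectrum: a dense integer vector of length 4^k whose
#' w-th entry is the number of length-k windows equal to the word with index
#' w (see [kmer_index()]).  Windows containing `N` are skipped and do not
#' contribute to `total_windows`.  A sequence shorter than k yields an
#' all-zero spectrum.
#'
#' @param seq A single residue string over `{A,C,G,T,N}`.
#' @param k Word length (1..14).
#' @return An object of class `kmer_spectrum`: a list with elements `k`,
#'   `counts` (length 4^k), `total_windows` (number of N-free windows) and
#'   `seq_length`.
#' @examples
#' s <- count_kmers("ACGTACGT", 2)
#' s$total_windows  # 7
#' @export
count_kmers <- function(seq, k) {
  k <- .check_k(k)
  stopifnot(is.character(seq), length(seq) == 1L)
  codes <- .encode_bases(seq)
  L <- length(codes)
  nbins <- 4L^k
  if (L < k) {
    return(structure(list(k = k, counts = integer(nbins), total_windows = 0L,
                          seq_length = L), class = "kmer_spectrum"))
  }
  nw <- L - k + 1L
  # Horner accumulation of the base-4 index over each window; one vectorised
  # pass per word position.  NA (from N) propagates and flags the window.
  idx <- numeric(nw)
  for (j in 0L:(k - 1L)) {
    idx <- idx * 4 + codes[(1L + j):(nw + j)]
  }
  idx <- idx[!is.na(idx)]
  counts <- tabulate(idx + 1, nbins = nbins)
  structure(list(k = k, counts = counts, total_windows = length(idx),
                 seq_length = L), class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum: k =", x$k, "| sequence length", x$seq_length,
      "|", x$total_windows, "valid windows |",
      sum(x$counts > 0), "distinct words\n")
  invisible(x)
}

#' Relative k-mer frequencies of a spectrum
#'
#' @param spectrum A `kmer_spectrum`.
#' @return Numeric vector of length 4^k summing to 1 (all zeros when the
#'   spectrum has no valid window).
#' @export
kmer_frequencies <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (spectrum$total_windows == 0L) {
    return(numeric(length(spectrum$counts)))
  }
  spectrum$counts / spectrum$total_windows
}

#' Merge spectra into a 4^k-by-N frequency matrix
#'
#' Column j holds the relative k-mer frequencies of sequence j.  Columns from
#' spectra with no valid window are all zero and reported in the
#' `"zero_columns"` attribute.
#'
#' @param spectra List of `kmer_spectrum` objects sharing the same k.
#' @param labels Optional column labels (default: names of `spectra`).
#' @return Numeric matrix with 4^k rows and one column per spectrum; row
#'   names are the k-mer words for k <= 6.
#' @export
kmer_frequency_matrix <- function(spectra, labels = names(spectra)) {
  if (length(spectra) == 0L) stop("no spectra supplied", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "kmer_spectrum")))
  ks <- vapply(spectra, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) {
    stop("all spectra must share the same k (got ",
         paste(sort(unique(ks)), collapse = ", "), ")", call. = FALSE)
  }
  k <- ks[1L]
  m <- vapply(spectra, kmer_frequencies, numeric(4^k))
  if (!is.matrix(m)) m <- matrix(m, ncol = length(spectra))
  if (!is.null(labels)) colnames(m) <- labels
  if (k <= 6L) rownames(m) <- kmer_word(0:(4^k - 1), k)
  zero <- which(vapply(spectra, `[[`, integer(1), "total_windows") == 0L)
  attr(m, "zero_columns") <- zero
  m
}

#' Write a spectrum as a tab-separated table
#'
#' Rows are k-mer word, count, relative frequency, ordered by index.  Only
#' words with nonzero count are written unless `all = TRUE`.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param path Output path ("" for stdout).
#' @param all Write all 4^k rows, including zero counts.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path = "", all = FALSE) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  idx <- if (all) seq_along(spectrum$counts) else which(spectrum$counts > 0)
  freq <- kmer_frequencies(spectrum)
  df <- data.frame(kmer = kmer_word(idx - 1, spectrum$k),
                   count = spectrum$counts[idx],
                   frequency = freq[idx])
  write.table(df, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
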