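#' @name kmer_measures
#' @title The seven k-mer distance measures
#' @description
#' Measures operate on the k-mer spectra of two sequences:
#' \describe{
#'   \item{Ch, Ma, Eu}{Chebyshev, Manhattan and Euclidean distances between
#'     the relative-frequency vectors (columns of the 4^k-by-N frequency
#'     matrix), so that sequence length does not dominate.}
#'   \item{d2}{Half of one minus the cosine similarity of the raw count
#'     vectors.}
#'   \item{d2star, d2S}{The same half-one-minus-correlation transform applied
#'     to counts centered by an order-M Markov background model fitted to
#'     each sequence, with the d2star (variance-like) or d2S
#'     (self-normalising) denominator.}
#'   \item{Hao}{Cosine dissimilarity of composition vectors: the relative
#'     deviation of observed k-mer frequencies from the order-(k-2) Markov
#'     prediction \eqn{f_0(w) = f(prefix) f(suffix) / f(middle)}.  Requires
#'     k >= 3.}
#' }
#' The four correlation-type measures lie in `[0, 1]` up to sign effects:
#' negative correlations map above 0.5 and are not clipped.
NULL

.MEASURES <- c("Ch", "Ma", "Eu", "Hao", "d2", "d2S", "d2star")

.check_measure <- function(measure, k, M) {
  measure <- match.arg(measure, .MEASURES)
  k <- .check_k(k)
  if (measure == "Hao" && k < 3L) {
    stop("the Hao measure requires k >= 3 (its background model has order k - 2)",
         call. = FALSE)
  }
  if (measure %in% c("d2S", "d2star")) {
    if (length(M) != 1L || is.na(M) || M < 0L || M != as.integer(M)) {
      stop("measure ", measure, " requires a Markov order M >= 0", call. = FALSE)
    }
    if (M >= k) stop("M must be smaller than k", call. = FALSE)
  }
  measure
}

.check_same_k <- function(s1, s2) {
  stopifnot(inherits(s1, "kmer_spectrum"), inherits(s2, "kmer_spectrum"))
  if (s1$k != s2$k) stop("spectra have different k", call. = FALSE)
  if (s1$total_windows == 0L || s2$total_windows == 0L) {
    stop("distance undefined for a spectrum with no valid window", call. = FALSE)
  }
}

#' Geometric distance between two frequency vectors
#'
#' @param f1,f2 Relative-frequency vectors of equal length (4^k).
#' @param measure One of `"Ch"` (Chebyshev, max absolute difference),
#'   `"Ma"` (Manhattan, sum of absolute differences) or `"Eu"` (Euclidean).
#' @return Nonnegative distance; `Ma <= 2` for probability vectors.
#' @export
geometric_distance <- function(f1, f2, measure = c("Ch", "Ma", "Eu")) {
  measure <- match.arg(measure)
  if (length(f1) != length(f2)) {
    stop("frequency vectors have different lengths", call. = FALSE)
  }
  d <- abs(f1 - f2)
  switch(measure, Ch = max(d), Ma = sum(d), Eu = sqrt(sum(d^2)))
}

#' d2 distance between two spectra
#'
#' Half of one minus the cosine similarity of the raw count vectors:
#' \eqn{\frac12 (1 - \sum_w c_{1w} c_{2w} / (\|c_1\| \|c_2\|))}.
#'
#' @param s1,s2 `kmer_spectrum` objects with the same k and at least one
#'   valid window each.
#' @return Distance in `[0, 1]`.
#' @export
d2_distance <- function(s1, s2) {
  .check_same_k(s1, s2)
  c1 <- as.numeric(s1$counts)
  c2 <- as.numeric(s2$counts)
  0.5 * (1 - sum(c1 * c2) / (sqrt(sum(c1^2)) * sqrt(sum(c2^2))))
}

# Centered counts and the p>0 support for the d2S/d2star family.  Words with
# zero expected probability under either background model are dropped: their
# centered contribution is ill-defined.
.centered_pair <- function(s1, s2, m1, m2, p1 = NULL, p2 = NULL) {
  .check_same_k(s1, s2)
  stopifnot(inherits(m1, "markov_model"), inherits(m2, "markov_model"))
  if (is.null(p1)) p1 <- expected_kmer_probs(m1, s1$k)
  if (is.null(p2)) p2 <- expected_kmer_probs(m2, s2$k)
  keep <- p1 > 0 & p2 > 0
  if (!any(keep)) {
    stop("distance undefined: every word has zero expected probability",
         call. = FALSE)
  }
  n1 <- s1$total_windows
  n2 <- s2$total_windows
  list(keep = keep,
       e1 = n1 * p1[keep], e2 = n2 * p2[keep],
       ch1 = s1$counts[keep] - n1 * p1[keep],
       ch2 = s2$counts[keep] - n2 * p2[keep])
}

#' d2star distance between two spectra
#'
#' Counts are centered by each sequence's own background model,
#' \eqn{\hat c_{iw} = c_{iw} - n_i p_{iw}}, and correlated with the
#' variance-like normaliser \eqn{\sqrt{n_1 p_{1w} n_2 p_{2w}}}; the
#' normalised correlation is mapped to \eqn{\frac12(1 - r)}.
#'
#' @param s1,s2 `kmer_spectrum` objects with the same k.
#' @param m1,m2 `markov_model`s fitted to the respective source sequences.
#' @param p1,p2 Optional precomputed [expected_kmer_probs()] vectors.
#' @return Distance in `[0, 1]` (values above 0.5 indicate negative
#'   correlation and are not clipped).
#' @export
d2star_distance <- function(s1, s2, m1, m2, p1 = NULL, p2 = NULL) {
  cp <- .centered_pair(s1, s2, m1, m2, p1, p2)
  num <- sum(cp$ch1 * cp$ch2 / sqrt(cp$e1 * cp$e2))
  den <- sqrt(sum(cp$ch1^2 / cp$e1)) * sqrt(sum(cp$ch2^2 / cp$e2))
  if (den == 0) {
    stop("distance undefined: zero-norm centered spectrum", call. = FALSE)
  }
  0.5 * (1 - num / den)
}

#' d2S distance between two spectra
#'
#' As [d2star_distance()] but with the self-normalising denominator
#' \eqn{a_w = \sqrt{\hat c_{1w}^2 + \hat c_{2w}^2}}; terms with
#' \eqn{a_w = 0} are skipped.
#'
#' @inheritParams d2star_distance
#' @return Distance in `[0, 1]` up to sign effects.
#' @export
d2s_distance <- function(s1, s2, m1, m2, p1 = NULL, p2 = NULL) {
  cp <- .centered_pair(s1, s2, m1, m2, p1, p2)
  a <- sqrt(cp$ch1^2 + cp$ch2^2)
  nz <- a > 0
  if (!any(nz)) {
    stop("distance undefined: all centered counts are zero", call. = FALSE)
  }
  num <- sum(cp$ch1[nz] * cp$ch2[nz] / a[nz])
  den <- sqrt(sum(cp$ch1[nz]^2 / a[nz])) * sqrt(sum(cp$ch2[nz]^2 / a[nz]))
  if (den == 0) {
    stop("distance undefined: zero-norm centered spectrum", call. = FALSE)
  }
  0.5 * (1 - num / den)
}

#' Composition vector of a sequence (Hao)
#'
#' The relative deviation of each observed k-mer frequency from its
#' order-(k-2) Markov prediction \eqn{f_0(w) = f(w_{1..k-1}) f(w_{2..k}) /
#' f(w_{2..k-1})}; components with \eqn{f_0(w) = 0} are set to 0.
#'
#' @param sk Spectrum at k (k >= 3).
#' @param sk1,sk2 Spectra of the same sequence at k-1 and k-2.
#' @return Numeric vector of length 4^k.
#' @export
composition_vector <- function(sk, sk1, sk2) {
  stopifnot(inherits(sk, "kmer_spectrum"), inherits(sk1, "kmer_spectrum"),
            inherits(sk2, "kmer_spectrum"))
  k <- sk$k
  if (k < 3L) stop("the composition vector requires k >= 3", call. = FALSE)
  if (sk1$k != k - 1L || sk2$k != k - 2L) {
    stop("auxiliary spectra must have orders k - 1 and k - 2", call. = FALSE)
  }
  f <- kmer_frequencies(sk)
  f1 <- kmer_frequencies(sk1)
  f2 <- kmer_frequencies(sk2)
  w <- 0:(4^k - 1)
  prefix <- w %/% 4L                    # first k-1 bases
  suffix <- w %% 4^(k - 1)              # last k-1 bases
  middle <- suffix %/% 4L               # bases 2..k-1
  f0 <- f1[prefix + 1] * f1[suffix + 1] / ifelse(f2[middle + 1] > 0,
                                                 f2[middle + 1], 1)
  f0[f2[middle + 1] == 0] <- 0
  a <- numeric(4^k)
  pos <- f0 > 0
  a[pos] <- (f[pos] - f0[pos]) / f0[pos]
  a
}

#' Hao (composition vector) distance between two sequences
#'
#' Half of one minus the cosine correlation of the two composition vectors
#' (see [composition_vector()]).
#'
#' @param s1,s2 Spectra at k for the two sequences.
#' @param aux1,aux2 For each sequence, a list with elements `km1` and `km2`:
#'   its spectra at k-1 and k-2.
#' @return Distance in `[0, 1]` up to sign effects.
#' @export
hao_distance <- function(s1, s2, aux1, aux2) {
  .check_same_k(s1, s2)
  a1 <- composition_vector(s1, aux1$km1, aux1$km2)
  a2 <- composition_vector(s2, aux2$km1, aux2$km2)
  n1 <- sqrt(sum(a1^2))
  n2 <- sqrt(sum(a2^2))
  if (n1 == 0 || n2 == 0) {
    stop("distance undefined: zero-norm composition vector", call. = FALSE)
  }
  0.5 * (1 - sum(a1 * a2) / (n1 * n2))
}

#' Pairwise k-mer distance matrix
#'
#' Computes the symmetric N-by-N matrix of pairwise distances between
#' sequences under one measure.  Spectra, background models and expected
#' probabilities are computed once per sequence and reused across all pairs.
#'
#' @param seqs Named character vector of residue strings (e.g. from
#'   [read_fasta()]), N >= 2.
#' @param measure One of `"Ch"`, `"Ma"`, `"Eu"`, `"Hao"`, `"d2"`, `"d2S"`,
#'   `"d2star"`.
#' @param k Word length.
#' @param M Markov background order for `d2S`/`d2star` (default 0); ignored
#'   by the other measures (Hao fixes its background order to k - 2
#'   internally).
#' @return Symmetric numeric matrix with zero diagonal and the sequence ids
#'   as dimnames.
#' @examples
#' seqs <- c(a = "ACGTACGTACGT", b = "ACGTACGAACGT", c = "TTTTGGGGCCCC")
#' kmer_distance_matrix(seqs, "d2", k = 2)
#' @export
kmer_distance_matrix <- function(seqs, measure = "d2star", k = 9L, M = 0L) {
  measure <- .check_measure(measure, k, M)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)

  spectra <- lapply(seqs, count_kmers, k = k)
  freqs <- models <- probs <- aux <- NULL
  if (measure %in% c("Ch", "Ma", "Eu")) {
    freqs <- lapply(spectra, kmer_frequencies)
  } else if (measure %in% c("d2S", "d2star")) {
    models <- lapply(seqs, fit_markov, M = M)
    probs <- lapply(models, expected_kmer_probs, k = k)
  } else if (measure == "Hao") {
    aux <- lapply(seqs, function(s) {
      list(km1 = count_kmers(s, k - 1L), km2 = count_kmers(s, k - 2L))
    })
  }

  pair_dist <- function(i, j) {
    switch(measure,
      Ch = , Ma = , Eu = geometric_distance(freqs[[i]], freqs[[j]], measure),
      d2 = d2_distance(spectra[[i]], spectra[[j]]),
      d2star = d2star_distance(spectra[[i]], spectra[[j]],
                               models[[i]], models[[j]],
                               probs[[i]], probs[[j]]),
      d2S = d2s_distance(spectra[[i]], spectra[[j]],
                         models[[i]], models[[j]],
                         probs[[i]], probs[[j]]),
      Hao = hao_distance(spectra[[i]], spectra[[j]], aux[[i]], aux[[j]])
    )
  }

  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(pair_dist(i, j), error = function(e) {
        stop("distance (", ids[i], ", ", ids[j], "): ", conditionMessage(e),
             call. = FALSE)
      })
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
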