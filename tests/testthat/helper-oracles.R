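# Independent naive oracles used to pin the vectorised implementation.
# Everything here works on word strings and dictionary (named-vector)
# counts, never touching the package's index transform or its vectorised
# spectrum/probability code.

BASES <- c("A", "C", "G", "T")

random_dna <- function(len, n_frac = 0) {
  alpha <- BASES
  x <- sample(alpha, len, replace = TRUE)
  if (n_frac > 0) {
    nn <- rbinom(1, len, n_frac)
    if (nn > 0) x[sample.int(len, nn)] <- "N"
  }
  paste(x, collapse = "")
}

# All 4^k words in base-4 index order (last character cycles fastest).
all_words <- function(k) {
  g <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(as.list(g)))
}

# Base-4 value of a word computed through string/strtoi machinery only.
word_index_oracle <- function(words) {
  strtoi(chartr("ACGT", "0123", words), base = 4L)
}

# Sliding-window dictionary count; windows containing N are dropped.
naive_counts <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(integer(0))
  w <- substring(seq, 1:(L - k + 1), k:L)
  w <- w[!grepl("N", w, fixed = TRUE)]
  if (!length(w)) return(integer(0))
  tab <- table(w)
  setNames(as.integer(tab), names(tab))
}

naive_freqs <- function(seq, k) {
  cts <- naive_counts(seq, k)
  cts / sum(cts)
}

dict_get <- function(dict, word) {
  v <- unname(dict[word])
  ifelse(is.na(v), 0, v)
}

# Full 4^k relative-frequency vector in index order, from the dictionary.
naive_freq_vector <- function(seq, k) {
  f <- naive_freqs(seq, k)
  out <- numeric(4^k)
  out[word_index_oracle(names(f)) + 1] <- f
  out
}

# Expected probability of each 4^k word under the order-M Markov model of
# seq, assembled position by position from dictionary counts and string
# slicing (never the package's index transform).
naive_markov_probs <- function(seq, k, M) {
  cm1 <- naive_counts(seq, M + 1)           # (M+1)-mer counts
  words <- all_words(k)
  if (M == 0) {
    base_p <- dict_get(cm1, BASES) / sum(cm1)
    p <- rep(1, length(words))
    for (j in 1:k) p <- p * base_p[match(substr(words, j, j), BASES)]
    return(p)
  }
  cm <- naive_counts(seq, M)                # M-mer counts
  nM <- sum(cm)
  ctxs <- all_words(M)
  # context count as an (M+1)-window prefix; unobserved context -> uniform
  prefix_counts <- vapply(ctxs, function(ctx) {
    sum(dict_get(cm1, paste0(ctx, BASES)))
  }, numeric(1))
  trans <- matrix(0.25, length(ctxs), 4)
  obs <- prefix_counts > 0
  for (b in 1:4) {
    trans[obs, b] <- dict_get(cm1, paste0(ctxs[obs], BASES[b])) /
      prefix_counts[obs]
  }
  p <- dict_get(cm, substr(words, 1, M)) / nM
  for (j in (M + 1):k) {
    ctx <- substr(words, j - M, j - 1)
    b <- substr(words, j, j)
    p <- p * trans[cbind(match(ctx, ctxs), match(b, BASES))]
  }
  p
}

# Naive per-word-loop evaluations of the seven measures, on raw sequences.
naive_measure <- function(seq1, seq2, measure, k, M = 0) {
  if (measure %in% c("Ch", "Ma", "Eu")) {
    f1 <- naive_freq_vector(seq1, k)
    f2 <- naive_freq_vector(seq2, k)
    d <- 0
    for (i in seq_along(f1)) {
      di <- abs(f1[i] - f2[i])
      d <- switch(measure, Ch = max(d, di), Ma = d + di, Eu = d + di^2)
    }
    return(if (measure == "Eu") sqrt(d) else d)
  }
  c1d <- naive_counts(seq1, k)
  c2d <- naive_counts(seq2, k)
  words <- all_words(k)
  c1 <- dict_get(c1d, words)
  c2 <- dict_get(c2d, words)
  if (measure == "d2") {
    num <- n1 <- n2 <- 0
    for (i in seq_along(words)) {
      num <- num + c1[i] * c2[i]
      n1 <- n1 + c1[i]^2
      n2 <- n2 + c2[i]^2
    }
    return(0.5 * (1 - num / (sqrt(n1) * sqrt(n2))))
  }
  if (measure %in% c("d2S", "d2star")) {
    p1 <- naive_markov_probs(seq1, k, M)
    p2 <- naive_markov_probs(seq2, k, M)
    n1 <- sum(c1)
    n2 <- sum(c2)
    num <- s1 <- s2 <- 0
    for (i in seq_along(words)) {
      if (p1[i] <= 0 || p2[i] <= 0) next    # ill-defined centering: drop
      ch1 <- c1[i] - n1 * p1[i]
      ch2 <- c2[i] - n2 * p2[i]
      if (measure == "d2star") {
        num <- num + ch1 * ch2 / sqrt(n1 * p1[i] * n2 * p2[i])
        s1 <- s1 + ch1^2 / (n1 * p1[i])
        s2 <- s2 + ch2^2 / (n2 * p2[i])
      } else {
        a <- sqrt(ch1^2 + ch2^2)
        if (a == 0) next
        num <- num + ch1 * ch2 / a
        s1 <- s1 + ch1^2 / a
        s2 <- s2 + ch2^2 / a
      }
    }
    return(0.5 * (1 - num / (sqrt(s1) * sqrt(s2))))
  }
  if (measure == "Hao") {
    cv <- function(seq) {
      f <- naive_freqs(seq, k)
      f1 <- naive_freqs(seq, k - 1)
      f2 <- naive_freqs(seq, k - 2)
      fp <- dict_get(f1, substr(words, 1, k - 1))
      fs <- dict_get(f1, substr(words, 2, k))
      fm <- dict_get(f2, substr(words, 2, k - 1))
      fw <- dict_get(f, words)
      f0 <- ifelse(fm > 0, fp * fs / fm, 0)
      a <- numeric(length(words))
      ok <- f0 > 0
      a[ok] <- (fw[ok] - f0[ok]) / f0[ok]
      a
    }
    a1 <- cv(seq1)
    a2 <- cv(seq2)
    num <- s1 <- s2 <- 0
    for (i in seq_along(words)) {
      num <- num + a1[i] * a2[i]
      s1 <- s1 + a1[i]^2
      s2 <- s2 + a2[i]^2
    }
    return(0.5 * (1 - num / (sqrt(s1) * sqrt(s2))))
  }
  stop("unknown measure in oracle")
}

# Package-side pair distance dispatched from raw sequences, mirroring the
# per-pair operations (used to compare against naive_measure()).
pkg_measure <- function(seq1, seq2, measure, k, M = 0) {
  s1 <- count_kmers(seq1, k)
  s2 <- count_kmers(seq2, k)
  switch(measure,
    Ch = , Ma = , Eu =
      geometric_distance(kmer_frequencies(s1), kmer_frequencies(s2), measure),
    d2 = d2_distance(s1, s2),
    d2star = d2star_distance(s1, s2, fit_markov(seq1, M), fit_markov(seq2, M)),
    d2S = d2s_distance(s1, s2, fit_markov(seq1, M), fit_markov(seq2, M)),
    Hao = hao_distance(s1, s2,
                       list(km1 = count_kmers(seq1, k - 1),
                            km2 = count_kmers(seq1, k - 2)),
                       list(km1 = count_kmers(seq2, k - 1),
                            km2 = count_kmers(seq2, k - 2))))
}

# Point-mutate a sequence: each site changes to a different uniform base
# with probability p.
mutate_seq <- function(seq, p) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < p & x != "N")
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1),
                     character(1))
  }
  paste(x, collapse = "")
}
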