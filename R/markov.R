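#' Fit an order-M Markov background model to one sequence
#'
#' Maximum-likelihood estimates from the sequence's own N-free windows:
#' `P(b | context) = count(context b) / count(context as (M+1)-window prefix)`.
#' The initial-state distribution is the empirical frequency of all 4^M
#' words (for M = 0, the single empty context with frequency 1).  Contexts
#' never observed as a prefix get a uniform transition row so that short
#' sequences degrade gracefully; their indices are recorded in
#' `uniform_contexts`.
#'
#' @param seq A residue string over `{A,C,G,T,N}`.
#' @param M Model order (>= 0).
#' @return An object of class `markov_model`: list with `order`,
#'   `state_freqs` (length 4^M), `transition` (4^M-by-4 row-stochastic
#'   matrix) and `uniform_contexts`.
#' @examples
#' m <- fit_markov("AACC", 0)
#' m$transition  # base composition (0.5, 0.5, 0, 0)
#' @export
fit_markov <- function(seq, M) {
  if (length(M) != 1L || is.na(M) || M < 0L || M != as.integer(M)) {
    stop("M must be a single integer >= 0", call. = FALSE)
  }
  M <- as.integer(M)
  sp1 <- count_kmers(seq, M + 1L)
  if (sp1$total_windows == 0L) {
    stop("sequence has no N-free window of length M + 1 = ", M + 1L,
         "; use a smaller M", call. = FALSE)
  }
  nctx <- 4L^M
  # (M+1)-mer counts laid out context-major: index = ctx*4 + base.
  tcounts <- matrix(sp1$counts, nrow = nctx, ncol = 4L, byrow = TRUE)
  rs <- rowSums(tcounts)
  trans <- tcounts / ifelse(rs > 0, rs, 1)
  uniform <- which(rs == 0)
  trans[uniform, ] <- 0.25
  if (M == 0L) {
    state <- 1
  } else {
    spM <- count_kmers(seq, M)
    state <- spM$counts / spM$total_windows
  }
  structure(list(order = M, state_freqs = state, transition = trans,
                 uniform_contexts = uniform),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov background model: order", x$order, "|",
      length(x$uniform_contexts), "unobserved context(s)\n")
  invisible(x)
}

#' Expected probability of one k-mer under a background model
#'
#' `p_w = Pr(w_1..w_M) * prod_{j=M+1..k} P(w_j | w_{j-M}..w_{j-1})`, with the
#' leading factor taken from the empirical M-mer frequencies.  For M = 0 this
#' is the product of base frequencies.
#'
#' @param model A `markov_model`.
#' @param word An N-free word of length k >= M.
#' @return A probability in `[0, 1]`.
#' @export
expected_kmer_prob <- function(model, word) {
  stopifnot(inherits(model, "markov_model"))
  M <- model$order
  codes <- .encode_bases(word)
  if (anyNA(codes)) stop("word contains a non-ACGT character", call. = FALSE)
  k <- length(codes)
  if (k < M) stop("word shorter than the model order M = ", M, call. = FALSE)
  ctx <- 0L
  if (M > 0L) for (c in codes[seq_len(M)]) ctx <- ctx * 4L + c
  p <- model$state_freqs[ctx + 1L]
  if (k > M) {
    for (j in (M + 1L):k) {
      p <- p * model$transition[ctx + 1L, codes[j] + 1L]
      ctx <- (ctx * 4L + codes[j]) %% 4L^M
    }
  }
  unname(p)
}

#' Expected probabilities of all 4^k k-mers
#'
#' Vectorised form of [expected_kmer_prob()]: returns the full length-4^k
#' vector indexed by [kmer_index()], built by extending the M-mer
#' distribution one base at a time.  Sums to 1 whenever every observed
#' context row does.
#'
#' @param model A `markov_model`.
#' @param k Word length (>= model order).
#' @return Numeric vector of length 4^k.
#' @export
expected_kmer_probs <- function(model, k) {
  stopifnot(inherits(model, "markov_model"))
  k <- .check_k(k)
  M <- model$order
  if (k < M) stop("k must be >= the model order M = ", M, call. = FALSE)
  p <- as.numeric(model$state_freqs)
  if (k == M) return(p)
  nctx <- 4L^M
  for (m in M:(k - 1L)) {
    ctx <- (seq_len(4^m) - 1) %% nctx
    # row w of ext holds the four extensions of word w, so t() flattens to
    # the index order w*4 + b
    ext <- model$transition[ctx + 1L, , drop = FALSE] * p
    p <- as.vector(t(ext))
  }
  p
}
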