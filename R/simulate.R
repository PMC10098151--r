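#' Random binary tree with uniform branch lengths
#'
#' Random binary topology with branch lengths drawn uniformly from
#' `br_range`; deterministic given `seed`.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param br_range Length-2 numeric: branch-length range (expected
#'   substitutions per site).
#' @param seed Optional integer seed.
#' @param labels Optional leaf labels (default `t1..tn`).
#' @return A rooted binary [ape::phylo] tree.
#' @export
random_phylo <- function(n_leaves, br_range = c(0.1, 2), seed = NULL,
                         labels = NULL) {
  if (n_leaves < 3L) stop("need at least 3 leaves", call. = FALSE)
  stopifnot(length(br_range) == 2L, all(br_range >= 0))
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_leaves,
                   br = function(n) runif(n, br_range[1L], br_range[2L]))
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_leaves)
    tr$tip.label <- labels
  }
  tr
}

#' Evolve sequences along a tree under an equal-rates model
#'
#' The root sequence is i.i.d. uniform over `{A,C,G,T}`.  Along a branch of
#' length t (expected substitutions per site) each site changes to a
#' uniformly chosen different base with probability
#' \eqn{p = \frac34 (1 - e^{-4t/3})} (the Jukes-Cantor transition
#' probability).  No indels; all leaf sequences have the root length.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param root_length Sequence length in bases.
#' @param seed Optional integer seed.
#' @return Named character vector of leaf sequences (names = tip labels).
#' @export
evolve_sequences <- function(tree, root_length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            root_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- length(tree$tip.label)
  root <- n + 1L
  L <- as.integer(root_length)
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE) - 1L
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    p <- 0.75 * (1 - exp(-4 * t / 3))
    s <- seqs[[parent]]
    hit <- which(runif(L) < p)
    if (length(hit)) {
      # uniformly one of the three other bases
      s[hit] <- (s[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    }
    seqs[[child]] <- s
  }
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(n),
                function(i) paste(bases[seqs[[i]] + 1L], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  out
}

#' Simulate a full test dataset: truth tree plus leaf sequences
#'
#' Convenience wrapper around [random_phylo()] and [evolve_sequences()]
#' drawing all randomness from one seed.
#'
#' @param n_leaves Number of taxa.
#' @param root_length Sequence length in bases.
#' @param br_range Branch-length range in expected substitutions per site.
#' @param seed Optional integer seed.
#' @return List with elements `tree` (the generating [ape::phylo]) and
#'   `seqs` (named character vector of leaf sequences).
#' @export
simulate_dataset <- function(n_leaves, root_length, br_range = c(0.01, 0.05),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- random_phylo(n_leaves, br_range = br_range)
  seqs <- evolve_sequences(tree, root_length)
  list(tree = tree, seqs = seqs)
}
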