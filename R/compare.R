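#' Nontrivial bipartitions of a tree
#'
#' Each internal edge of the unrooted tree splits the leaf set in two; the
#' split is canonicalised as the sorted block that does not contain the
#' pivot leaf (the alphabetically smallest label).  Trivial splits (a block
#' of size < 2) are excluded, so a fully resolved unrooted tree with n
#' leaves yields exactly n - 3 bipartitions.
#'
#' @param tree An [ape::phylo] tree (rooted trees are unrooted first).
#' @return A character vector of canonical split keys, each the
#'   comma-separated sorted block; the full blocks are attached as the
#'   `"blocks"` attribute.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree has duplicate leaf labels", call. = FALSE)
  }
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  pivot <- sort(tree$tip.label)[1L]
  tree <- ape::reorder.phylo(tree, "postorder")
  # accumulate descendant tip sets bottom-up over the postorder edge list
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  internal <- which(tree$edge[, 2L] > n)
  keys <- character(0)
  blocks <- list()
  for (e in internal) {
    blk <- below[[tree$edge[e, 2L]]]
    if (length(blk) < 2L || length(blk) > n - 2L) next
    if (pivot %in% blk) blk <- setdiff(tree$tip.label, blk)
    blk <- sort(blk)
    key <- paste(blk, collapse = ",")
    if (!key %in% keys) {
      keys <- c(keys, key)
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  structure(keys, blocks = blocks)
}

#' Robinson-Foulds symmetric difference between two trees
#'
#' The number of nontrivial bipartitions present in exactly one of the two
#' trees over the same leaf set.  Trees are treated as unrooted.  For two
#' fully resolved trees on n leaves the value lies in `[0, 2(n - 3)]`.
#'
#' @param t1,t2 [ape::phylo] trees with identical leaf label sets.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf label sets", call. = FALSE)
  }
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Relative accuracy of a target method against a reference
#'
#' Both methods are scored against the same truth tree by their
#' Robinson-Foulds symmetric difference; the relative accuracy is
#' `rf_reference / rf_target`, so values above 1 mean the target is closer
#' to the truth than the reference, and the reference method itself scores
#' exactly 1.  (The inverse ratio is recoverable as `1 / accuracy`.)
#'
#' @param rf_target Symmetric difference of the target method's tree.
#' @param rf_reference Symmetric difference of the reference method's tree.
#' @return Nonnegative real; `Inf` when the target is perfect and the
#'   reference is not; 1 when both are perfect.
#' @export
relative_accuracy <- function(rf_target, rf_reference) {
  stopifnot(rf_target >= 0, rf_reference >= 0)
  if (rf_target == 0) {
    if (rf_reference == 0) return(1)
    warning("target tree matches the truth exactly; relative accuracy is infinite")
    return(Inf)
  }
  rf_reference / rf_target
}
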