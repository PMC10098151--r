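.check_dist_matrix <- function(D, min_n = 2L) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D))
  if (nrow(D) != ncol(D) || nrow(D) < min_n) {
    stop("distance matrix must be square with at least ", min_n, " taxa",
         call. = FALSE)
  }
  if (anyNA(D) || any(!is.finite(D))) {
    stop("distance matrix contains NA or non-finite entries", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: the closest pair of clusters is
#' merged at height d/2 and the distance of the merged cluster to every
#' other is the size-weighted arithmetic mean of its members' distances.
#' The result is a rooted ultrametric tree; on an ultrametric input matrix
#' the tree's leaf-to-leaf path lengths reproduce the input exactly.
#'
#' @param D Symmetric distance matrix (or `dist`) with taxon labels.
#' @return A rooted ultrametric [ape::phylo] tree.
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' ape::write.tree(upgma(D))  # ((a:1,b:1):1,c:2)
#' @export
upgma <- function(D) {
  D <- .check_dist_matrix(D, min_n = 2L)
  tr <- ape::as.phylo(hclust(as.dist(D), method = "average"))
  ape::reorder.phylo(tr, "postorder")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration via [ape::nj()]: the pair minimising the
#' Q-criterion is joined, limb lengths follow the standard formulas, and the
#' final three clusters meet at a trifurcating root, so the tree is
#' effectively unrooted.  NJ is consistent: an additive matrix yields the
#' generating topology with its exact branch lengths.  Negative branch
#' lengths (possible on non-additive input) are clamped to zero with the
#' deficit transferred to the sibling branch, preserving path lengths
#' through the parent node.
#'
#' @param D Symmetric distance matrix (or `dist`) with taxon labels; N >= 3
#'   (N = 2 falls back to a single cherry).
#' @param clamp_negative Clamp negative branch lengths (default `TRUE`).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D, clamp_negative = TRUE) {
  D <- .check_dist_matrix(D, min_n = 2L)
  if (nrow(D) == 2L) {
    lab <- rownames(D)
    return(ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                         lab[1], D[1, 2] / 2,
                                         lab[2], D[1, 2] / 2)))
  }
  tr <- ape::nj(as.dist(D))
  if (clamp_negative) tr <- .clamp_negative_edges(tr)
  tr
}

# Set each negative edge length to zero and add the (negative) deficit to a
# sibling edge at the same parent node, so the distance between the two
# subtrees hanging off that node is preserved.
.clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs)) {
      s <- sibs[which.max(tr$edge.length[sibs])]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
      # if the sibling in turn went negative the loop picks it up
      if (tr$edge.length[s] < 0) next
    }
    if (!any(tr$edge.length < 0)) break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Serialise a tree to a Newick string
#'
#' Standard Newick with branch lengths and a terminating semicolon; labels
#' containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree An [ape::phylo] tree.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string.
#' @export
to_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  needs_quote <- grepl("[ \t(),:;\\[\\]']", tree$tip.label)
  tree$tip.label[needs_quote] <-
    paste0("'", gsub("'", "''", tree$tip.label[needs_quote]), "'")
  ape::write.tree(tree, digits = digits)
}
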