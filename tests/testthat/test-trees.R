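random_labeled_matrix <- function(tree) {
  D <- cophenetic(tree)
  D[sort(rownames(D)), sort(rownames(D))]
}

test_that("UPGMA reproduces the hand-executed worked example", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- upgma(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  cd <- cophenetic(tr)
  expect_equal(cd["a", "b"], 2)
  expect_equal(cd["a", "c"], 4)
  # heights 1 then 2: ultrametric with root-to-leaf depth 2
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
})

test_that("UPGMA on two taxa splits the distance at the root", {
  D <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- upgma(D)
  expect_equal(sort(tr$edge.length), c(3, 3))
})

test_that("UPGMA recovers random ultrametric matrices exactly", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(4:16, 1)
    truth <- ape::rcoal(n)
    D <- cophenetic(truth)
    tr <- upgma(D)
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
    cd <- cophenetic(tr)
    expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-9)
  }
})

test_that("NJ recovers the worked additive 4-taxon example exactly", {
  D <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  # topology AB|CD
  expect_equal(attr(tree_bipartitions(tr), "blocks"), list(c("C", "D")))
  # branch lengths (A:1, B:2, internal:1, C:3, D:4)
  lens <- setNames(tr$edge.length,
                   ifelse(tr$edge[, 2] <= 4, tr$tip.label[tr$edge[, 2]], "int"))
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)
  expect_equal(lens[["D"]], 4)
  expect_equal(lens[["int"]], 1)
  # path lengths reproduce the additive matrix
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("NJ is consistent on additive matrices from random trees", {
  set.seed(52)
  for (rep in 1:10) {
    truth <- ape::rtree(8, br = function(n) runif(n, 0.1, 2))
    D <- cophenetic(truth)
    tr <- nj_tree(D)
    expect_equal(rf_distance(tr, truth), 0)
    expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("equidistant taxa give zero internal branch lengths", {
  n <- 5
  D <- matrix(1, n, n) - diag(n)
  rownames(D) <- colnames(D) <- letters[1:n]
  tr <- nj_tree(D)
  internal <- tr$edge[, 2] > n
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("negative branch lengths are clamped without changing topology", {
  set.seed(53)
  # non-additive random matrices routinely drive NJ limbs negative
  found_negative <- FALSE
  for (rep in 1:20) {
    n <- 6
    Dn <- matrix(runif(n * n), n, n)
    Dn <- (Dn + t(Dn)) / 2
    diag(Dn) <- 0
    rownames(Dn) <- colnames(Dn) <- letters[1:n]
    raw <- nj_tree(Dn, clamp_negative = FALSE)
    clamped <- nj_tree(Dn)
    if (any(raw$edge.length < 0)) found_negative <- TRUE
    expect_true(all(clamped$edge.length >= 0))
    expect_equal(rf_distance(raw, clamped), 0)
  }
  expect_true(found_negative)
})

test_that("tree construction is stable under taxon permutation", {
  set.seed(54)
  truth <- ape::rtree(10, br = function(n) runif(n, 0.1, 1))
  D <- cophenetic(truth)
  perm <- sample(10)
  for (builder in list(upgma, nj_tree)) {
    t1 <- builder(D)
    t2 <- builder(D[perm, perm])
    expect_equal(rf_distance(t1, t2), 0)
  }
})

test_that("Newick serialisation round-trips topology and branch lengths", {
  set.seed(55)
  tr <- ape::rtree(9, br = function(n) runif(n, 0.01, 2))
  back <- ape::read.tree(text = to_newick(tr))
  expect_equal(rf_distance(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_match(to_newick(tr), ";$")
  # two-leaf cherry
  D <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_newick(nj_tree(D)), "(a:3,b:3);")
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgma(D), "not symmetric")
  D2 <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D2), "NA or non-finite")
})
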