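test_that("geometric distances evaluate the closed forms", {
  f1 <- c(1, 0, 0, 0)
  f2 <- c(0, 1, 0, 0)
  expect_equal(geometric_distance(f1, f1, "Ch"), 0)
  expect_equal(geometric_distance(f1, f2, "Ch"), 1)
  expect_equal(geometric_distance(f1, f2, "Ma"), 2)
  expect_equal(geometric_distance(f1, f2, "Eu"), sqrt(2))
  expect_error(geometric_distance(f1, c(1, 0), "Eu"), "length")
})

test_that("d2 is half one-minus-cosine of the count vectors", {
  s <- count_kmers("ACGTACGTGG", 2)
  expect_equal(d2_distance(s, s), 0)
  expect_equal(d2_distance(count_kmers("AAAA", 2), count_kmers("CCCC", 2)), 0.5)
  expect_error(d2_distance(count_kmers("AC", 3), count_kmers("ACGT", 3)),
               "no valid window")
})

test_that("centered measures are zero on identical inputs", {
  set.seed(31)
  seq <- random_dna(600)
  s <- count_kmers(seq, 3)
  for (M in 0:1) {
    m <- fit_markov(seq, M)
    expect_equal(d2star_distance(s, s, m, m), 0, tolerance = 1e-12)
    expect_equal(d2s_distance(s, s, m, m), 0, tolerance = 1e-12)
  }
  aux <- list(km1 = count_kmers(seq, 2), km2 = count_kmers(seq, 1))
  expect_equal(hao_distance(s, s, aux, aux), 0, tolerance = 1e-12)
})

test_that("all seven measures match the naive per-word oracles", {
  set.seed(32)
  cases <- expand.grid(k = 2:4, M = 0:1)
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]
    M <- cases$M[i]
    for (rep in 1:2) {
      s1 <- random_dna(sample(200:600, 1), 0.02)
      s2 <- random_dna(sample(200:600, 1), 0.02)
      for (meas in c("Ch", "Ma", "Eu", "d2", "d2S", "d2star", "Hao")) {
        if (meas == "Hao" && k < 3) next
        expect_equal(pkg_measure(s1, s2, meas, k, M),
                     naive_measure(s1, s2, meas, k, M),
                     tolerance = 1e-10,
                     label = sprintf("%s k=%d M=%d", meas, k, M))
      }
    }
  }
})

test_that("Hao composition vector is invariant under exact duplication", {
  set.seed(33)
  seq <- random_dna(800)
  # an N spacer removes boundary windows, so counts exactly double
  dup <- paste(seq, seq, sep = "N")
  d <- pkg_measure(seq, dup, "Hao", 4)
  expect_equal(d, 0, tolerance = 1e-6)
})

test_that("d2star centers away shared-composition signal for i.i.d. pairs", {
  set.seed(34)
  s1 <- random_dna(50000)
  s2 <- random_dna(50000)
  d <- pkg_measure(s1, s2, "d2star", 5, 0)
  expect_equal(d, 0.5, tolerance = 0.1)
})

test_that("metric axioms hold across measures on random sequence sets", {
  set.seed(35)
  seqs <- setNames(replicate(4, random_dna(400, 0.02)), paste0("s", 1:4))
  for (meas in c("Ch", "Ma", "Eu", "d2", "d2S", "d2star", "Hao")) {
    D <- kmer_distance_matrix(seqs, meas, k = 3, M = 1)
    expect_equal(D, t(D), tolerance = 1e-12)
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
    if (meas == "Ma") expect_true(all(D <= 2))
    if (meas %in% c("d2", "d2S", "d2star", "Hao")) {
      expect_true(all(D <= 1 + 1e-12))
    }
  }
})

test_that("batch matrix equals independently computed single pairs", {
  set.seed(36)
  seqs <- setNames(replicate(5, random_dna(300)), paste0("s", 1:5))
  D <- kmer_distance_matrix(seqs, "d2star", k = 4, M = 0)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(D[i, j], pkg_measure(seqs[[i]], seqs[[j]], "d2star", 4, 0),
                   tolerance = 1e-12)
    }
  }
  # identical sequences give the all-zero matrix
  D0 <- kmer_distance_matrix(c(a = seqs[[1]], b = seqs[[1]]), "d2", k = 4)
  expect_equal(unname(D0), matrix(0, 2, 2))
})

test_that("undefined pair distances carry the pair identity", {
  seqs <- c(good = strrep("ACGT", 30), short = "AC")
  expect_error(kmer_distance_matrix(seqs, "d2", k = 4), "good.*short")
})

test_that("parameter validation enforces measure constraints", {
  seqs <- c(a = strrep("ACGT", 20), b = strrep("AAGT", 20))
  expect_error(kmer_distance_matrix(seqs, "Hao", k = 2), "k >= 3")
  expect_error(kmer_distance_matrix(seqs, "d2star", k = 3, M = 3), "smaller than k")
  expect_error(kmer_distance_matrix(seqs, "d2star", k = 3, M = -1), "M >= 0")
  expect_error(kmer_distance_matrix(seqs[1], "d2", k = 3), "at least two")
})

test_that("mean d2star distance increases with substitution rate", {
  set.seed(37)
  rates <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4)
  anc <- random_dna(1500)
  mean_d <- vapply(rates, function(p) {
    mean(replicate(8, {
      pkg_measure(mutate_seq(anc, p), mutate_seq(anc, p), "d2star", 4, 0)
    }))
  }, numeric(1))
  expect_gt(cor(rates, mean_d, method = "spearman"), 0.9)
})
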