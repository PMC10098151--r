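Package: kmerphylo
Title: Alignment-Free Phylogenetics from k-mer Spectrum Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phylogenetic trees from unaligned nucleotide sequences.
    Counts k-mers with a base-4 index transform, computes pairwise distances
    under seven k-mer statistics (Chebyshev, Manhattan, Euclidean, the
    composition-vector measure of Hao, and the d2, d2S and d2star statistics
    with order-M Markov background models), constructs UPGMA or
    neighbor-joining trees, and scores inferred trees against a reference
    topology by the Robinson-Foulds symmetric difference.  Includes a
    sequence simulator (equal-rates substitution along a random tree) so the
    whole pipeline can be exercised without external data, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
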