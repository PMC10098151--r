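---
title: "Alignment-free phylogenetics with k-mer spectrum distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogenetics with k-mer spectrum distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerphylo)
```

## The method

`kmerphylo` infers phylogenies without aligning sequences. The pipeline has
four steps:

1. **Counting.** Every length-k window of a sequence is mapped to an integer
   in `[0, 4^k)` by reading it as a base-4 number (`A,C,G,T = 0,1,2,3`,
   first base most significant), and counted into a dense array. Windows
   containing `N` are skipped entirely, and the number of valid windows `n`
   shrinks accordingly; this avoids biasing counts toward any base.
2. **Frequency matrix.** The per-sequence counts are merged into a
   `4^k`-by-`N` matrix of relative frequencies `f_w = c_w / n`.
3. **Distances.** One of seven statistics turns a pair of spectra into a
   dissimilarity (below), giving an `N`-by-`N` symmetric matrix.
4. **Tree building.** UPGMA (average-linkage clustering; rooted,
   ultrametric) or neighbor joining (Saitou–Nei; unrooted) is applied to
   the matrix.

Inferred trees are scored against a reference topology by the
Robinson–Foulds symmetric difference — the number of internal-edge
bipartitions present in exactly one of the two trees — and two methods are
compared by `relative_accuracy(rf_target, rf_reference) =
rf_reference / rf_target`, so values above 1 mean the target method is
closer to the truth. The inverse reading ("ratio of target's and
reference's symmetric difference") is recoverable as `1/accuracy`; we chose
the orientation in which "x% more accurate" maps to a ratio above 1.

## The seven measures

With counts `c_iw`, valid-window totals `n_i` and frequencies `f_iw`:

* **Chebyshev / Manhattan / Euclidean** operate on frequencies, not raw
  counts, so that sequence length does not dominate:
  `Ch = max_w |f_1w − f_2w|`, `Ma = Σ_w |f_1w − f_2w|`,
  `Eu = √Σ_w (f_1w − f_2w)²`.
* **d2** is half one-minus-cosine of the raw count vectors; identical
  spectra give 0, spectra with disjoint word sets give 0.5.
* **d2star and d2S** first center the counts by a background model:
  `ĉ_iw = c_iw − n_i p_iw`, where `p_iw` is the expected probability of
  word `w` under an order-`M` Markov model fitted to sequence `i` itself.
  The correlation `Σ_w ĉ_1w ĉ_2w / D_w` (with `D_w = √(n_1 p_1w n_2 p_2w)`
  for d2star, `D_w = √(ĉ_1w² + ĉ_2w²)` for d2S) is normalised by the
  corresponding self-terms and mapped through `½(1 − r)`. Centering removes
  the shared-composition signal that dominates d2, which is why two
  unrelated i.i.d. sequences score ≈ 0.5 under d2star but can look similar
  under d2.
* **Hao** (the composition-vector measure) predicts each k-mer frequency
  from its two (k−1)-mers and central (k−2)-mer,
  `f⁰_w = f(prefix)·f(suffix)/f(middle)` — an order-(k−2) Markov
  prediction — and correlates the relative deviations
  `a_w = (f_w − f⁰_w)/f⁰_w`. It therefore requires `k ≥ 3` and takes no
  separate `M`.

The four correlation-type measures live in `[0, 1]`; a negative correlation
maps above 0.5 and is deliberately not clipped, since clipping would
discard ordering information among very distant pairs.

### Background models

Each sequence gets its *own* order-`M` model, the standard choice for the
d2-family statistics: transition probabilities are maximum-likelihood
ratios of (M+1)-mer to M-mer window counts, and the initial factor of a
word's probability uses the empirical M-mer frequencies. Contexts never
observed receive a uniform transition row rather than an error, so short
sequences degrade gracefully (the affected contexts are recorded on the
model object). Words with zero expected probability under either model are
dropped from the d2star/d2S sums — their centered contribution is
ill-defined — and with `M = 0` on realistic sequences this never triggers.

## Tunable parameters

* **k** (word length, default 9): the resolution of the spectrum. Larger k
  resolves more distant relationships but needs longer sequences; with
  fewer than `4^k` windows the spectrum is sparse and the statistics get
  noisy. The command-line default drops to 6 when the mean sequence length
  is below `4^9`, and the drop is logged. `k` is capped at 14, where the
  dense count array reaches ~1 GiB.
* **M** (background order for d2S/d2star, default 0): order 0 centers by
  base composition alone; orders 1–2 absorb dinucleotide/trinucleotide
  structure. `M` must be below `k`.
* **measure** (default d2star): d2star is generally the most accurate for
  phylogenetic reconstruction in our simulations; Eu is the cheapest.
* **method** (default NJ): NJ is consistent on additive matrices and is the
  default; UPGMA assumes a molecular clock (ultrametric input).

## Numerical and degenerate-input choices

* Counting uses a vectorised Horner (powers-of-4) accumulation over window
  positions — algebraically the rolling-index update, one pass, linear in
  sequence length; after an `N` the affected windows simply drop out via
  `NA` propagation.
* A sequence shorter than k yields an all-zero spectrum with zero windows —
  flagged, not an error — but distances on such spectra are errors carrying
  the offending pair's identity.
* UPGMA merges ties in `hclust`'s deterministic order; NJ inherits
  `ape::nj`'s deterministic tie-breaking: runs are bit-reproducible.
* NJ can produce negative branch lengths on non-additive input; they are
  clamped to zero with the deficit transferred to a sibling branch, which
  preserves path lengths through the parent node and never changes the
  topology.
* Newick output keeps 10 significant digits; round-tripping a tree through
  Newick reproduces branch lengths to better than 1e-9.
* Rooted trees are unrooted before Robinson–Foulds comparison, so UPGMA and
  NJ trees are scored on the same footing; bipartitions are canonicalised
  as the block avoiding the alphabetically smallest leaf.

## What the simulator does (and does not) emulate

`simulate_dataset()` draws a random binary topology with branch lengths
uniform on a configurable range — the default `c(0.01, 0.05)` expected
substitutions per site gives moderately hard, realistically short internal
edges for a 12-taxon recovery experiment — and evolves an i.i.d.-uniform
root sequence of fixed length down the tree. Substitution is equal-rates
(Jukes–Cantor): along a branch of length `t` each site moves to one of the
three other bases with total probability `¾(1 − e^(−4t/3))`, which composes
exactly like the JC transition matrix. There are **no indels, no rate
heterogeneity, no base-composition bias, and no alignment error**, so
passing recovery tests demonstrates the correctness and statistical
behaviour of the distance/tree machinery — not performance on real rRNA or
genome data, where indels and compositional drift both help (alignment-free
methods tolerate indels) and hurt (background models must absorb
composition bias).

The default study conditions for the end-to-end experiment — 12 leaves,
5000-base sequences, d2star with `k = 6`, `M = 0`, NJ, 20 replicates — are
sized so the whole experiment runs in seconds. Under these conditions
recovery hinges on internal edges of ~0.01 substitutions/site, i.e. ~50
expected substitutions on a 5 kb sequence; with ~`4^6` ≈ 4096 words and
only ~5000 windows, the d2star spectrum carries roughly one count per word,
and the shortest edges sit at the edge of its resolving power. An aligned
Jukes–Cantor NJ baseline resolves the same replicates, which locates the
difficulty in the statistic's variance, not in the data or the tree
builder.

## Limitations

* Nucleotide alphabets only; protein spectra would need different alphabet
  handling and measure parameterisations.
* Forward-strand counting by default; `--reverse-complement` adds the other
  strand by counting the sequence concatenated (behind an `N` spacer) with
  its reverse complement.
* Dense spectra: memory is `O(4^k)` per retained spectrum, which is why k
  is capped and why whole-genome use should prefer `k ≤ 12`.
* No bootstrap support values, no BIONJ/FastME refinements, no
  branch-length-aware tree distances.
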