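---
title: "q-Gram density profiles, PCA embedding, and UPGMA phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{q-Gram density profiles, PCA embedding, and UPGMA phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgramfir)
```

## The model

`qgramfir` compares equal-length DNA sequences without alignment by
looking at the *positional* distribution of their words. The pipeline
has four stages.

**1. Bin signatures.** For word length $q$ the $4^q$ possible q-grams
("bins") are enumerated lexicographically ($A < C < G < T$). For a
sequence of length $n$ and a bin $b_j$, the signature $S_j$ is the
binary vector of length $n - q + 1$ whose entry $\alpha$ is 1 iff the
q-gram starting at position $\alpha$ equals $b_j$. For an N-free
sequence every window belongs to exactly one bin, so the signatures
sum to the all-ones vector — a completeness invariant the tests
exercise.

**2. FIR density.** Each signature is smoothed by a causal
finite-impulse-response filter
$$y[n] = \sum_{i=0}^{k} b_i\, x[n-i],$$
with zero initial conditions and output truncated to the input length
(*not* full linear convolution — the worked 6-base example below pins
this choice down: a full convolution would have length 9). With the
default uniform unit window of width $W$ ($k = W - 1$, all $b_i = 1$),
$y_j[i]$ counts occurrences of bin $j$ starting in signature positions
$\max(1, i-W+1), \dots, i$: the filter *is* a trailing-window
occurrence counter, and the tests assert exact equality against an
independent brute-force counter.

```{r example}
p <- density_profile("AACTCG", q = 1, b = c(0.2, 0.1, 0.3, 0.4))
p$rows
```

**3. PCA embedding.** The per-bin density rows of each sequence are
concatenated bin-major into a data matrix $D$ of size
$m \times 4^q(n-q+1)$ (for $q=1$: the four nucleotide densities
simultaneously, $4n$ columns). Columns are mean-centered but *not*
scaled to unit variance: all columns are densities in the same unit,
so covariance PCA is the appropriate form (and the embedding is
deliberately not scale-invariant). Scores are projections onto the top
$k=3$ right singular vectors of the centered matrix — computed via SVD
rather than an explicit covariance for stability when
$p \gg m$. Explained-variance fractions are always reported relative
to the total variance over *all* components.

**4. Dissimilarity and tree.** The dissimilarity value (DV) between
two sequences is the Euclidean distance between their score rows,
stored condensed in the pair order $(2,1), (3,1), \dots, (m,m-1)$
(the serialization of `stats::dist`). UPGMA agglomerates the DV
matrix: the minimum pair merges at height $d_{\min}/2$, and the
distance from the merged cluster to any other is the size-weighted
mean over all cross-cluster taxon pairs. The result is a rooted
ultrametric tree; the tree-derived genetic distance between two taxa
is their cophenetic distance (twice the height of their lowest common
ancestor), and `write_newick()` exports branch lengths so every
leaf-to-root path equals the root height.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `q` | 1 | word length; `4^q` bins (guard at `q <= 12`) |
| `window` (`W`) | 10 | FIR window width in signature positions |
| `normalize` | `FALSE` | taps `1/W` instead of 1 (densities in `[0,1]`) |
| `k` | 3 | retained principal components |
| `clusters` | none | optional flat cut of the UPGMA tree |

There is no universally correct $W$: it trades positional resolution
against smoothing. Small $W$ keeps fine positional detail but makes
profiles noisy under point mutation; large $W$ approaches global
q-gram counts and discards position. The default $W = 10$ is a
moderate smoothing for the few-hundred-bp sequences this method is
aimed at, and the pipeline logs the $W$ in use on every run so it is
never silently assumed. `normalize` rescales all densities by the same
constant and therefore never changes the tree topology, only the DV
scale.

$k = 3$ matches the visualisable 3D embedding the method was designed
around; with $g$ well-separated groups, $g-1$ components suffice, so
$k = 3$ is exactly right for four groups and a reasonable compromise
beyond.

## Numerical choices

* **Sign convention.** Each loading vector is flipped so its
  largest-magnitude entry is positive, making runs bit-reproducible.
  Euclidean distances downstream are sign-invariant, so this affects
  only the reported score coordinates.
* **Degenerate input.** A data matrix with zero total variance (e.g.
  identical sequences) is refused with a "degenerate data" error; this
  is diagnosed before the $k \le m-1$ bound so the message names the
  actual problem.
* **UPGMA ties.** Equal minima (within a $10^{-12}$ relative guard)
  are resolved to the lowest (column, row) cluster-index pair, making
  the merge order deterministic.
* **Ambiguity codes.** `N` is accepted and retained; any q-gram window
  touching an `N` matches no bin, so signature column sums may drop
  below 1 there. All other non-ACGT characters are rejected loudly
  with the record id and position rather than silently coerced.
  Unequal sequence lengths are an error: no length normalization is
  attempted.
* **Text round-trips.** Numeric TSV artifacts carry 12 significant
  digits and Newick exports 15, so re-chaining stages through files
  stays within the test tolerances.
* **Worked-example discrepancy.** In the 6-base reference calculation
  the `C` signature of `AACTCG` is `[0 0 1 0 1 0]` (positions 3 *and*
  5). A published variant of this example omits the second occurrence
  yet reports a filtered row consistent with it at positions 3–6 only;
  this package always uses the scan-derived signature, so its `C` row
  is `[0.0 0.0 0.2 0.1 0.5 0.5]`.

## The synthetic generator, and what passing tests show

`generate_clustered_dataset()` emulates families of equal-length
sequences diverged from a common ancestor by point mutation: a uniform
random root, one ancestor per family mutated from the root at
`inter_rate`, and members mutated from their ancestor at `intra_rate`.
Substitutions are Jukes–Cantor-like (uniform over the three other
bases) with no indels, so the equal-length precondition holds by
construction. A single master seed spawns per-draw sub-seeds (root,
each ancestor, each member) so datasets are reproducible from one
integer.

The reference validation setting — 4 families × 3 members, 300 bp,
`intra = 0.01`, `inter = 0.30` — mirrors the scale of a small
multi-species gene panel, and the test suite requires the full
pipeline (q = 1, unit W = 10, k = 3, 4-cluster cut) to recover the
true partition on at least 95 of 100 seeds; a 10-sequence 444-bp
variant with unequal family sizes (2, 5, 2, 1) serves as a structural
stand-in for a real hemoglobin panel. These problem sizes keep the
default test run fast while still exercising every stage end to end.

What this does *not* show: real sequences have indels (forcing users
to pre-trim to equal length), transition/transversion bias, rate
heterogeneity along the sequence, and base composition drift — none of
which the generator models. Passing the recovery criterion
demonstrates that the pipeline separates families whose divergence is
dominated by substitutions; it does not certify accuracy of the DV
scale as an evolutionary distance, which is unit-dependent (on $W$ and
`normalize`) by construction.

## Known limitations

* Sequences must be equal length; the package refuses rather than
  normalizes.
* The DV/tree-height scale depends on $W$ and `normalize`; compare
  trees, not raw DVs, across differently configured runs.
* UPGMA assumes a molecular clock (ultrametricity); strongly uneven
  rates will distort the topology, as with any average-linkage tree.
* No FASTQ, alignment formats, or sequence downloading; no
  neighbor-joining, bootstrap, or plotting in the core.
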