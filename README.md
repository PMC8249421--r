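# qgramfir

Alignment-free comparison of equal-length DNA sequences through
FIR-filtered q-gram density profiles, PCA embedding, and UPGMA
phylogeny.

## The problem and the method

Alignment-based phylogenetics becomes expensive (and brittle) for
divergent sequences. `qgramfir` instead compares sequences by *where*
their words occur. For a word length `q` there are `4^q` possible
q-grams ("bins"), ordered lexicographically. For each bin `b_j` of a
sequence `seq`, the **bin signature** `S_j` is the 0/1 vector of length
`|seq| − q + 1` marking every start position where `b_j` occurs. A
causal finite-impulse-response (FIR) filter with coefficients
`b_0 … b_k`,

    y[n] = Σ_{i=0..k} b_i · x[n − i]    (x[m] = 0 for m < 1, |y| = |x|)

slides over each signature; with the default uniform unit window of
width `W` the output `y_j[i]` is simply the number of occurrences of
bin `j` starting in the trailing `W` signature positions — a local
**word-density profile** along the sequence.

For `m` sequences of common length `n`, the per-bin density rows are
concatenated (bin-major) into a data matrix `D` of size
`m × 4^q(n − q + 1)`; for `q = 1` this analyses the four nucleotide
densities simultaneously in `4n` columns. Covariance PCA (columns
mean-centered, no variance scaling) projects `D` onto `k = 3` score
components; the **dissimilarity value (DV)** between two sequences is
the Euclidean distance between their score rows, serialized in the
condensed pair order `(2,1), (3,1), …, (m,m−1)`. UPGMA
(size-weighted average linkage) on the DV matrix yields a rooted
ultrametric tree — merge heights are `d_min/2`, the tree-derived
genetic distance between taxa is the cophenetic distance — exported as
Newick.

A synthetic-family generator (uniform random root, per-family ancestors
at an `inter` substitution rate, members at an `intra` rate; no indels)
makes the whole pipeline testable without downloading real accessions.

## Worked example

The package's reference calculation, a 6-base sequence filtered with a
4-tap window:

```r
library(qgramfir)
p <- density_profile("AACTCG", q = 1, b = c(0.2, 0.1, 0.3, 0.4))
p$rows
#>   [,1] [,2] [,3] [,4] [,5] [,6]
#> A  0.2  0.3  0.4  0.7  0.4  0.0
#> C  0.0  0.0  0.2  0.1  0.5  0.5
#> G  0.0  0.0  0.0  0.0  0.0  0.2
#> T  0.0  0.0  0.0  0.2  0.1  0.3
```

Each row is the causal convolution of that nucleotide's bin signature
with the window: the A row peaks at 0.7 where both leading A's fall
inside the 4-tap window.

End-to-end on a synthetic 4-family dataset:

```r
d <- generate_clustered_dataset(family_spec(4, 3, 300, 0.01, 0.30, seed = 7))
fa <- tempfile(fileext = ".fa"); write_fasta(d$sequences, fa)
res <- run_pipeline(fa, q = 1, window = 10, k = 3, clusters = 4,
                    out_dir = "out")
#> read: m = 12 sequences, n = 300 bp
#> density: q = 1, W = 10 (unit weights), 4 bins x 300 positions
#> data matrix: 12 x 1200 (p = 4^q * (n - q + 1))
#> pca: k = 3, explained fractions 0.3752 0.2972 0.2819
#> cut: 4 clusters
#> wrote 7 artifacts to out
same_partition(res$clusters, d$labels)
#> [1] TRUE
```

The three retained components carry ~95% of the variance here (four
well-separated families need three axes), and the 4-cluster cut of the
UPGMA tree recovers the generating families exactly. `out/` contains
`density.tsv`, `scores.tsv`, `variance.json`, `dist.tsv` (the square DV
matrix), `tree.nwk`, `clusters.tsv`, and `run_metadata.json`.

The same stages are available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/qgramfir.R", package = "qgramfir"))')
Rscript $CLI simulate --families 4 --size 3 --length 300 \
        --intra 0.01 --inter 0.30 --seed 7 --out sim.fa --out-labels labels.tsv
Rscript $CLI run --fasta sim.fa --clusters 4 --out-dir out
```

`density`, `pca`, and `tree` subcommands chain the stages through their
text artifacts; `--config FILE` accepts a flat `key=value` file.

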