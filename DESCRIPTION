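Package: qgramfir
Title: Alignment-Free DNA Comparison via q-Gram Density FIR Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Alignment-free comparison of equal-length DNA sequences.
    Word (k-mer/q-gram) occurrences are encoded as binary bin signatures
    and smoothed into positional density profiles with a causal finite
    impulse response (FIR) sliding-window filter.  Per-sequence profiles
    are assembled into a data matrix, embedded with covariance principal
    component analysis, and pairwise Euclidean dissimilarities between
    the retained component scores feed a UPGMA hierarchical clustering
    that yields a rooted ultrametric phylogeny with Newick export.
    Includes a generator of synthetic sequence families for validation
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
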