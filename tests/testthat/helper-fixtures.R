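# Shared fixtures and independent oracles for the test suite.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(ids, seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fa)
  fa
}

# Brute-force oracle: number of occurrences of `bin` starting in the
# trailing window of W signature positions ending at position i.
trailing_count <- function(seq, bin, W) {
  q <- nchar(bin)
  L <- nchar(seq) - q + 1L
  occ <- vapply(seq_len(L),
                function(a) substr(seq, a, a + q - 1L) == bin, logical(1))
  vapply(seq_len(L), function(i) sum(occ[max(1L, i - W + 1L):i]), numeric(1))
}

# Independent PCA oracle: dense eigendecomposition of the covariance.
pca_oracle <- function(D, k) {
  Dc <- scale(D, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(Dc), symmetric = TRUE)
  scores <- Dc %*% eg$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores,
       explained = eg$values[seq_len(k)] / sum(pmax(eg$values, 0)))
}

# Random well-behaved dissimilarity matrix: Euclidean distances of a
# random point cloud (symmetric, zero diagonal, no exact ties a.s.).
random_dissimilarity <- function(m, dim = 3) {
  pts <- matrix(stats::rnorm(m * dim), m, dim)
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(paste0("t", seq_len(m)), paste0("t", seq_len(m)))
  dm
}

# Leaf-to-root path lengths of a rooted phylo with edge lengths.
root_to_leaf_depths <- function(phy) {
  nt <- length(phy$tip.label)
  depth <- numeric(nt + phy$Nnode)
  # edges are parent -> child; root has index nt + 1
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  stats::setNames(depth[seq_len(nt)], phy$tip.label)
}
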