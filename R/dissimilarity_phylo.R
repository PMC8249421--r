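#' Condensed pairwise Euclidean dissimilarities between score rows
#'
#' The dissimilarity value (DV) between two sequences is the Euclidean
#' distance between their retained principal-component score rows.  The
#' m(m-1)/2 values are serialized in the pair order
#' (2,1), (3,1), ..., (m,1), (3,2), ..., (m,m-1) — the standard
#' condensed (lower-triangle, column-major) layout of [stats::dist()].
#'
#' @param S A `score_matrix` from [pca_scores()], or a numeric matrix of
#'   score rows.
#' @return A [stats::dist] object with the sequence ids as labels.
#' @export
pairwise_euclidean_condensed <- function(S) {
  scores <- if (inherits(S, "score_matrix")) S$scores else as.matrix(S)
  if (nrow(scores) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  stats::dist(scores, method = "euclidean")
}

#' Square dissimilarity matrix from condensed distances
#'
#' @param d A `dist` object, or a condensed numeric vector whose length
#'   is a triangular number m(m-1)/2 (pair order as in
#'   [pairwise_euclidean_condensed()]).
#' @param ids Optional taxa labels (defaults to the `dist` labels).
#' @return Symmetric m x m matrix with zero diagonal.
#' @export
to_square <- function(d, ids = NULL) {
  if (!inherits(d, "dist")) {
    len <- length(d)
    m <- (1 + sqrt(1 + 8 * len)) / 2
    if (m != round(m)) {
      stop("condensed vector length ", len,
           " is not a triangular number m(m-1)/2", call. = FALSE)
    }
    if (len == 0L) {
      dm <- matrix(0, 1, 1)
      if (!is.null(ids)) dimnames(dm) <- list(ids, ids)
      return(dm)
    }
    attr(d, "Size") <- as.integer(m)
    attr(d, "Diag") <- FALSE
    attr(d, "Upper") <- FALSE
    class(d) <- "dist"
  }
  dm <- as.matrix(d)
  if (!is.null(ids)) dimnames(dm) <- list(ids, ids)
  dm
}

#' UPGMA hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerates taxa by repeatedly merging the pair of clusters at
#' minimum dissimilarity; the merged node sits at height d_min / 2 so
#' the tree is ultrametric in DV units.  After a merge, the distance
#' from the new cluster to any other is the size-weighted (arithmetic)
#' mean over all cross-cluster taxon pairs.  Ties (equal within 1e-12
#' relative) are broken by the lowest (row, column) cluster-index pair,
#' making the result deterministic.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and
#'   non-negative entries (taxa labels in dimnames), or a `dist` object.
#' @return An `upgma_tree`: list with hclust-style `merge` (m-1 by 2;
#'   negative entries are leaves), `height` (merge heights in tree
#'   units, i.e. d/2), `labels`, and `m`.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- as.matrix(dm)
  m <- nrow(dm)
  if (m < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (ncol(dm) != m) stop("dissimilarity matrix must be square",
                          call. = FALSE)
  if (!all(is.finite(dm))) stop("non-finite dissimilarities", call. = FALSE)
  if (any(dm < 0)) stop("negative dissimilarities", call. = FALSE)
  if (any(abs(dm - t(dm)) > 0)) stop("dissimilarity matrix is asymmetric",
                                     call. = FALSE)
  if (any(diag(dm) != 0)) stop("diagonal must be zero", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(m))

  d <- dm
  active <- seq_len(m)            # columns of d still in play
  node <- -seq_len(m)             # hclust coding: -leaf, +merge index
  size <- rep(1L, m)
  merge <- matrix(0L, m - 1L, 2L)
  height <- numeric(m - 1L)

  for (s in seq_len(m - 1L)) {
    na <- length(active)
    # global minimum over the lower triangle; values within the 1e-12
    # relative guard are ties, resolved to the lowest (col, row) pair
    # because we scan columns (then rows) in ascending index order and
    # only move on a strict improvement.
    best <- NULL
    vmin <- Inf
    for (j in seq_len(na - 1L)) {
      col <- d[active[(j + 1L):na], active[j]]
      i_rel <- which.min(col)          # first minimum: lowest row index
      v <- col[i_rel]
      if (is.null(best) || v < vmin - 1e-12 * max(1, abs(vmin))) {
        vmin <- v
        best <- c(j, j + i_rel)
      }
    }
    j <- best[1L]; i <- best[2L]
    aj <- active[j]; ai <- active[i]
    merge[s, ] <- sort(c(node[aj], node[ai]),
                       decreasing = FALSE)  # negatives (leaves) first
    height[s] <- vmin / 2
    # size-weighted average update into slot aj
    rest <- active[-c(j, i)]
    if (length(rest)) {
      newd <- (size[aj] * d[rest, aj] + size[ai] * d[rest, ai]) /
        (size[aj] + size[ai])
      d[rest, aj] <- newd
      d[aj, rest] <- newd
    }
    size[aj] <- size[aj] + size[ai]
    node[aj] <- s
    active <- active[-i]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 m = m),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree: %d taxa, root height %.6g\n",
              x$m, max(x$height)))
  invisible(x)
}

#' Convert a UPGMA tree to base-R hclust / ape phylo
#'
#' `as_hclust()` returns a [stats::hclust] object whose heights are the
#' merge dissimilarities (2 x tree height), the convention of
#' [stats::hclust()]; `as_phylo()` returns an [ape::phylo] whose
#' root-to-leaf path length equals the tree's root height.
#'
#' @param tree An `upgma_tree`.
#' @return An `hclust` or `phylo` object.
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  structure(list(merge = tree$merge,
                 height = 2 * tree$height,
                 order = hclust_order(tree$merge),
                 labels = tree$labels,
                 method = "average",
                 call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

# leaf ordering by left-to-right traversal of the merge tree
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @rdname as_hclust
#' @export
as_phylo <- function(tree) {
  ape::as.phylo(as_hclust(tree))
}

#' Cophenetic (tree-derived genetic) distance between two taxa
#'
#' Twice the height of the lowest common ancestor of `i` and `j` on the
#' ultrametric UPGMA tree; zero iff `i == j`.
#'
#' @param tree An `upgma_tree`.
#' @param i,j Taxa labels (or 1-based leaf indices).
#' @return Non-negative scalar distance in DV units.
#' @export
cophenetic_distance <- function(tree, i, j) {
  stopifnot(inherits(tree, "upgma_tree"))
  idx <- function(x) {
    if (is.character(x)) {
      p <- match(x, tree$labels)
      if (is.na(p)) stop("unknown taxon: ", x, call. = FALSE)
      p
    } else {
      if (x < 1 || x > tree$m) stop("taxon index out of range: ", x,
                                    call. = FALSE)
      as.integer(x)
    }
  }
  ii <- idx(i); jj <- idx(j)
  if (ii == jj) return(0)
  cd <- stats::cophenetic(as_hclust(tree))
  as.matrix(cd)[ii, jj]
}

#' Cut a UPGMA tree into k clusters
#'
#' Removes the k-1 highest merges and returns the resulting connected
#' groups, numbered contiguously from 1 in taxa order.
#'
#' @param tree An `upgma_tree`.
#' @param k Number of clusters, between 1 and the number of taxa.
#' @return Named integer vector mapping taxa labels to cluster indices.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  if (length(k) != 1L || k < 1 || k > tree$m || k != as.integer(k)) {
    stop("k must be an integer in [1, ", tree$m, "]", call. = FALSE)
  }
  stats::cutree(as_hclust(tree), k = as.integer(k))
}

#' Export / import a UPGMA tree as Newick
#'
#' Branch lengths are assigned so every leaf-to-root path length equals
#' the root height; parsing the string back yields the identical
#' topology and heights.
#'
#' @param tree An `upgma_tree`.
#' @return A Newick string (terminated by `;`).
#' @export
write_newick <- function(tree) {
  # 15 significant digits so a parse round-trip preserves heights
  ape::write.tree(as_phylo(tree), digits = 15)
}

#' @rdname write_newick
#' @param text A Newick string.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}
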