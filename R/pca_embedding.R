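#' Assemble per-sequence density profiles into the data matrix D
#'
#' Row i is the concatenation of sequence i's per-bin density rows in
#' lexicographic bin order (bin-major: all positions of the first bin,
#' then all positions of the second, ...).  With word length `q` and
#' sequence length `n` the matrix is m by `4^q * (n - q + 1)`; for the
#' mono-gram case this is the m-by-4n layout used for three-component
#' analysis of the four nucleotide densities simultaneously.
#'
#' @param profiles List of `density_profile` objects sharing `q`, the
#'   number of positions, and the filter used to build them.
#' @return A numeric matrix with sequence ids as rownames and
#'   `bin.position` column names, carrying attributes `q` and `bins`.
#' @export
build_data_matrix <- function(profiles) {
  if (length(profiles) < 2L) {
    stop("need at least 2 density profiles to compare", call. = FALSE)
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "density_profile")))
  qs <- unique(vapply(profiles, `[[`, integer(1), "q"))
  Ls <- unique(vapply(profiles, function(p) ncol(p$rows), integer(1)))
  if (length(qs) != 1L || length(Ls) != 1L) {
    stop("density profiles are heterogeneous (q: ",
         paste(qs, collapse = ","), "; positions: ",
         paste(Ls, collapse = ","), ")", call. = FALSE)
  }
  ids <- vapply(profiles, `[[`, character(1), "seq_id")
  bins <- profiles[[1L]]$bins
  D <- t(vapply(profiles, function(p) as.vector(t(p$rows)),
                numeric(length(bins) * Ls)))
  rownames(D) <- ids
  colnames(D) <- paste(rep(bins, each = Ls), rep(seq_len(Ls), length(bins)),
                       sep = ".")
  attr(D, "q") <- qs
  attr(D, "bins") <- bins
  D
}

#' Principal-component scores of the data matrix
#'
#' Columns of `D` are mean-centered (no variance scaling: the densities
#' already share one unit, so this is covariance PCA) and projected onto
#' the top `k` right singular vectors of the centered matrix.  Signs are
#' fixed deterministically: each loading vector is flipped so that its
#' largest-magnitude entry is positive.  Explained-variance fractions
#' are relative to the total variance over all components, not just the
#' retained ones.
#'
#' @param D Numeric data matrix (rows = sequences), e.g. from
#'   [build_data_matrix()].
#' @param k Number of components to retain; must satisfy
#'   `k <= min(nrow(D) - 1, ncol(D))`.
#' @return A `score_matrix`: list with `scores` (m by k, rownames kept),
#'   `explained_fraction` (length k), `sdev` (all components), and `k`.
#' @export
pca_scores <- function(D, k = 3) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("non-finite values in data matrix",
                               call. = FALSE)
  m <- nrow(D)
  p <- ncol(D)
  kmax <- min(m - 1L, p)
  if (length(k) != 1L || k < 1 || k != as.integer(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  # degeneracy is diagnosed before the k bound so identical sequences
  # fail with the informative message whatever k was requested
  if (sum(apply(D, 2, stats::var)) <= 1e-24 * p) {
    stop("degenerate data: total variance is zero", call. = FALSE)
  }
  if (k > kmax) {
    stop("k = ", k, " exceeds min(m - 1, p) = ", kmax, call. = FALSE)
  }
  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  # deterministic sign: largest-magnitude loading entry positive
  ncomp <- ncol(pc$rotation)
  for (c in seq_len(ncomp)) {
    top <- which.max(abs(pc$rotation[, c]))
    if (pc$rotation[top, c] < 0) {
      pc$rotation[, c] <- -pc$rotation[, c]
      pc$x[, c] <- -pc$x[, c]
    }
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_fraction = pc$sdev[seq_len(k)]^2 / total_var,
                 sdev = pc$sdev,
                 k = as.integer(k)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d sequences, %d components\n",
              nrow(x$scores), x$k))
  cat("explained variance fractions:",
      paste(sprintf("%.4f", x$explained_fraction), collapse = " "), "\n")
  invisible(x)
}
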