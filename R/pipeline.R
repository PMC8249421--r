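#' Run the full alignment-free comparison pipeline
#'
#' Executes, in order: FASTA reading and validation, per-sequence
#' q-gram density profiles via the causal FIR window, data-matrix
#' assembly, covariance PCA to `k` score components, condensed pairwise
#' Euclidean dissimilarities, UPGMA tree construction, and (optionally)
#' a k-cluster cut.  All artifacts are written to `out_dir` as text:
#' `density.tsv` (long format: seq_id, bin, position, density),
#' `scores.tsv`, `variance.json`, `dist.tsv` (square DV matrix),
#' `tree.nwk`, optionally `clusters.tsv`, and `run_metadata.json`.
#' Identical inputs and configuration give byte-identical numeric
#' outputs.
#'
#' @param fasta Path to the input multi-FASTA of equal-length sequences.
#' @param q Word length (default 1: the four single-nucleotide densities
#'   analysed simultaneously).
#' @param window Uniform FIR window width W in signature positions.
#'   There is no universally right W; the run log always states the one
#'   in use.
#' @param normalize Scale window taps to sum to 1 (densities in [0,1]
#'   instead of counts in [0,W]).
#' @param k Number of principal components retained (default 3).
#' @param clusters Optional number of clusters to cut the tree into.
#' @param out_dir Output directory (created if missing).  `NULL` skips
#'   all file output and just returns the results.
#' @param quiet Suppress informational logging.
#' @return Invisibly, a list with `sequences`, `profiles`, `D`,
#'   `scores`, `dist` (condensed), `dm` (square), `tree`, `newick`,
#'   `clusters` (or `NULL`), and `files` (written paths).
#' @export
run_pipeline <- function(fasta, q = 1, window = 10, normalize = FALSE,
                         k = 3, clusters = NULL, out_dir = NULL,
                         quiet = FALSE) {
  info <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  ss <- stage("read", read_fasta(fasta))
  info("read: m = %d sequences, n = %d bp", ss$m, ss$n)
  b <- stage("density", uniform_window(window, normalize = normalize))
  profiles <- stage("density", density_profiles(ss, q = q, b = b))
  info("density: q = %d, W = %d (%s), %d bins x %d positions",
       q, window, if (normalize) "normalized" else "unit weights",
       4^q, ss$n - q + 1)
  D <- stage("data-matrix", build_data_matrix(profiles))
  info("data matrix: %d x %d (p = 4^q * (n - q + 1))", nrow(D), ncol(D))
  S <- stage("pca", pca_scores(D, k = k))
  info("pca: k = %d, explained fractions %s", k,
       paste(sprintf("%.4f", S$explained_fraction), collapse = " "))
  dcond <- stage("distances", pairwise_euclidean_condensed(S))
  dm <- to_square(dcond)
  tree <- stage("upgma", upgma(dm))
  nwk <- write_newick(tree)
  cl <- NULL
  if (!is.null(clusters)) {
    cl <- stage("cut", cut_tree(tree, clusters))
    info("cut: %d clusters", clusters)
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_artifacts(out_dir, ss, profiles, S, dm, nwk, cl,
                             q = q, window = window,
                             normalize = normalize, k = k, fasta = fasta)
    info("wrote %d artifacts to %s", length(files), out_dir)
  }
  invisible(list(sequences = ss, profiles = profiles, D = D, scores = S,
                 dist = dcond, dm = dm, tree = tree, newick = nwk,
                 clusters = cl, files = files))
}

write_artifacts <- function(out_dir, ss, profiles, S, dm, nwk, cl,
                            q, window, normalize, k, fasta) {
  p <- function(f) file.path(out_dir, f)
  written <- c(density = p("density.tsv"), scores = p("scores.tsv"),
               variance = p("variance.json"), dist = p("dist.tsv"),
               newick = p("tree.nwk"), metadata = p("run_metadata.json"))

  write_density_tsv(profiles, written[["density"]])
  write_matrix_tsv(S$scores, written[["scores"]], row_name = "seq_id")
  jsonlite::write_json(
    list(k = S$k,
         explained_fraction = S$explained_fraction,
         total_components = length(S$sdev)),
    written[["variance"]], auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(dm, written[["dist"]], row_name = "id")
  writeLines(nwk, written[["newick"]])
  if (!is.null(cl)) {
    written[["clusters"]] <- p("clusters.tsv")
    utils::write.table(
      data.frame(seq_id = names(cl), cluster = unname(cl)),
      written[["clusters"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(tool = "qgramfir",
         version = as.character(utils::packageVersion("qgramfir")),
         q = q, window = window, normalize = normalize, k = k,
         m = ss$m, n = ss$n,
         input = basename(fasta),
         input_md5 = unname(tools::md5sum(fasta))),
    written[["metadata"]], auto_unbox = TRUE, digits = NA)
  written
}

# long format: seq_id, bin, position (1-based signature position), density
write_density_tsv <- function(profiles, path) {
  parts <- lapply(profiles, function(pr) {
    L <- ncol(pr$rows)
    data.frame(seq_id = pr$seq_id,
               bin = rep(pr$bins, each = L),
               position = rep(seq_len(L), length(pr$bins)),
               density = format_num(as.vector(t(pr$rows))),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, parts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read stage outputs back (for chaining CLI subcommands)
#'
#' @param path A TSV written by the pipeline (`scores.tsv` or
#'   `density.tsv`).
#' @return For scores: numeric matrix with seq_id rownames.  For
#'   densities: list of `density_profile` objects.
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_scores_tsv
#' @export
read_density_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  lapply(split(df, factor(df$seq_id, levels = unique(df$seq_id))),
         function(d) {
           bins <- unique(d$bin)
           L <- max(d$position)
           rows <- matrix(d$density, nrow = length(bins), ncol = L,
                          byrow = TRUE, dimnames = list(bins, NULL))
           structure(list(seq_id = d$seq_id[1],
                          q = nchar(bins[1]), bins = bins, rows = rows),
                     class = "density_profile")
         })
}
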