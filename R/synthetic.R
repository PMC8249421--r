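#' Point-mutate a DNA sequence
#'
#' Each base is independently substituted with probability `rate`; a
#' substituted base is replaced by one of the three other bases, drawn
#' uniformly (Jukes-Cantor-style, no indels, so length is preserved).
#' The same `(seq, rate, seed)` always yields the same output.
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param rate Per-base substitution probability in `[0, 0.75]`.
#' @param seed Optional integer seed for a self-contained draw; when
#'   `NULL` the current RNG stream is used.
#' @return Mutated DNA string of the same length.
#' @export
mutate <- function(seq, rate, seed = NULL) {
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate > 0.75) {
    stop("rate must lie in [0, 0.75]", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # uniform over the 3 alternatives: offset the current base's index
    cur <- match(chars[hit], bases)
    off <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- bases[((cur - 1L + off) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Specification of a synthetic family-structured dataset
#'
#' Describes equal-length sequence families diverged from a common
#' ancestor by point mutation: a uniform random root sequence, one
#' ancestor per family obtained by mutating the root at `inter_rate`,
#' and `family_size` members per family obtained by mutating the
#' ancestor at `intra_rate`.
#'
#' @param n_families Number of families (positive integer).
#' @param family_size Members per family; a scalar or a vector of
#'   length `n_families` for unequal family sizes.
#' @param seq_length Sequence length in bases.
#' @param intra_rate Within-family per-base substitution probability.
#' @param inter_rate Root-to-ancestor per-base substitution
#'   probability; must exceed `intra_rate` and be at most 0.75.
#' @param seed Integer master seed; all sub-draws are derived from it.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_families = 4, family_size = 3, seq_length = 300,
                        intra_rate = 0.01, inter_rate = 0.30, seed = 1) {
  stopifnot(n_families >= 1, all(family_size >= 1), seq_length >= 1)
  if (!(intra_rate >= 0 && intra_rate < inter_rate && inter_rate <= 0.75)) {
    stop("need 0 <= intra_rate < inter_rate <= 0.75", call. = FALSE)
  }
  sizes <- rep_len(as.integer(family_size), n_families)
  structure(list(n_families = as.integer(n_families), sizes = sizes,
                 seq_length = as.integer(seq_length),
                 intra_rate = intra_rate, inter_rate = inter_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a clustered synthetic sequence set with true labels
#'
#' The master seed deterministically spawns one sub-seed for the root
#' draw, one per family ancestor, and one per member, so the whole
#' dataset is reproducible from the single integer.
#'
#' @param spec A [family_spec()].
#' @return List with `sequences` (a `seq_set`, ids `f<family>_m<member>`)
#'   and `labels` (named integer vector: true family of each sequence).
#' @export
generate_clustered_dataset <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  total <- sum(spec$sizes)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  subseeds <- sample.int(.Machine$integer.max,
                         1L + spec$n_families + total)

  set.seed(subseeds[1L])
  root <- paste(sample(c("A", "C", "G", "T"), spec$seq_length,
                       replace = TRUE), collapse = "")
  ids <- character(total)
  seqs <- character(total)
  labels <- integer(total)
  r <- 0L
  for (f in seq_len(spec$n_families)) {
    ancestor <- mutate(root, spec$inter_rate,
                       seed = subseeds[1L + f])
    for (mm in seq_len(spec$sizes[f])) {
      r <- r + 1L
      ids[r] <- sprintf("f%d_m%d", f, mm)
      seqs[r] <- mutate(ancestor, spec$intra_rate,
                        seed = subseeds[1L + spec$n_families + r])
      labels[r] <- f
    }
  }
  names(labels) <- ids
  list(sequences = seq_set(ids, seqs), labels = labels)
}

#' Do two cluster assignments induce the same partition?
#'
#' Compares assignments up to relabeling of cluster indices.
#'
#' @param a,b Integer (or factor) vectors of equal length.
#' @return `TRUE` iff the induced set partitions are identical.
#' @export
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  ta <- split(seq_along(a), a)
  tb <- split(seq_along(b), b)
  if (length(ta) != length(tb)) return(FALSE)
  canon <- function(s) paste(vapply(s, paste, character(1), collapse = ","),
                             collapse = ";")
  key <- function(groups) canon(groups[order(vapply(groups, min, numeric(1)))])
  key(ta) == key(tb)
}
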