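#' Read and validate equal-length DNA sequences from FASTA
#'
#' Reads a (possibly gzip-compressed) multi-FASTA file and normalizes each
#' record: sequences are uppercased and RNA `U` is mapped to `T`.  After
#' normalization only the characters `A`, `C`, `G`, `T`, `N` are accepted;
#' any other character (including IUPAC ambiguity codes other than `N`)
#' aborts with an error naming the offending record and 1-based position.
#' The record id is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return A `seq_set` object: a list with elements `ids` (character),
#'   `seqs` (named character vector of equal-length DNA strings), `m`
#'   (number of records) and `n` (shared sequence length).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "aacucg", ">s2", "GGGTTT"), fa)
#' ss <- read_fasta(fa)
#' ss$seqs[["s1"]]  # "AACTCG"
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("no sequences in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(raw), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- vapply(seq_along(raw), function(i) {
    normalize_dna(as.character(raw[[i]]), id = ids[i])
  }, character(1))
  names(seqs) <- ids
  seq_set(ids, seqs)
}

#' @rdname read_fasta
#' @param ids Character vector of unique record ids.
#' @param seqs Character vector of normalized DNA strings, one per id.
#' @export
seq_set <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  seqs <- as.character(seqs)
  names(seqs) <- ids
  n <- validate_equal_length(seqs)
  structure(list(ids = ids, seqs = seqs, m = length(ids), n = n),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d sequences of length %d bp\n", x$m, x$n))
  invisible(x)
}

# Uppercase, U -> T, then reject anything outside {A,C,G,T,N} with the
# record id and 1-based position of the first offender.
normalize_dna <- function(seq, id = "<sequence>") {
  if (nchar(seq) == 0L) {
    stop("record '", id, "' has an empty sequence", call. = FALSE)
  }
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("record '%s' has illegal character '%s' at position %d",
                 id, substr(seq, bad, bad), bad), call. = FALSE)
  }
  seq
}

#' Assert that all sequences share one length
#'
#' @param records Character vector of sequences, or a `seq_set`.
#' @return The shared length `n` (invisibly usable as a scalar).
#' @export
validate_equal_length <- function(records) {
  if (inherits(records, "seq_set")) records <- records$seqs
  if (length(records) == 0L) stop("no sequences", call. = FALSE)
  lens <- unique(nchar(records))
  if (length(lens) != 1L) {
    stop("sequences have unequal lengths: ",
         paste(sort(lens), collapse = ", "), call. = FALSE)
  }
  lens
}

#' Write a sequence set to FASTA
#'
#' @param x A `seq_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  bs <- Biostrings::BStringSet(x$seqs)
  names(bs) <- x$ids
  Biostrings::writeXStringSet(bs, path)
  invisible(path)
}

# Numeric TSV writers shared by the pipeline stages: 12 significant digits
# so chained stages re-read from text stay within downstream tolerances.
format_num <- function(x) formatC(x, digits = 12, format = "g")

write_matrix_tsv <- function(mat, path, row_name = "id") {
  df <- data.frame(rownames(mat), apply(mat, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(row_name, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
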