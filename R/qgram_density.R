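#' Enumerate all q-gram bins in lexicographic order
#'
#' A bin is one word of `q` consecutive nucleotides over the alphabet
#' `{A, C, G, T}`.  There are `4^q` bins; they are returned sorted
#' lexicographically with `A < C < G < T`, the canonical ordering used
#' throughout the package for signature rows and data-matrix blocks.
#'
#' @param q Word length (positive integer, at most 12).
#' @return A `qgram_alphabet`: list with `q` and the character vector
#'   `bins` of length `4^q`.
#' @examples
#' enumerate_bins(1)$bins  # "A" "C" "G" "T"
#' head(enumerate_bins(2)$bins, 5)  # "AA" "AC" "AG" "AT" "CA"
#' @export
enumerate_bins <- function(q) {
  if (length(q) != 1L || is.na(q) || q != as.integer(q) || q < 1) {
    stop("q must be a positive integer", call. = FALSE)
  }
  if (q > 12) {
    stop("q = ", q, " exceeds the supported maximum of 12 (4^q bins)",
         call. = FALSE)
  }
  q <- as.integer(q)
  letters4 <- c("A", "C", "G", "T")
  grids <- rev(rep(list(letters4), q))
  bins <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  structure(list(q = q, bins = bins), class = "qgram_alphabet")
}

#' Binary bin signature of a sequence
#'
#' Marks every start position where the given bin occurs: element
#' `alpha` is 1 iff `substr(seq, alpha, alpha + q - 1) == bin`.  The
#' signature has `nchar(seq) - q + 1` elements.  Windows touching an
#' `N` never match any bin and contribute 0.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param bin A q-gram over `{A,C,G,T}`.
#' @return Integer vector of 0/1 of length `nchar(seq) - nchar(bin) + 1`.
#' @examples
#' bin_signature("AACTCG", "A")   # 1 1 0 0 0 0
#' bin_signature("AACTCG", "AA")  # 1 0 0 0 0
#' @export
bin_signature <- function(seq, bin) {
  stopifnot(length(seq) == 1L, length(bin) == 1L)
  n <- nchar(seq)
  q <- nchar(bin)
  if (q < 1L) stop("bin must be non-empty", call. = FALSE)
  if (q > n) {
    stop("bin length (", q, ") exceeds sequence length (", n, ")",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", bin)) {
    stop("bin must contain only A, C, G, T: ", bin, call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  binc <- strsplit(bin, "", fixed = TRUE)[[1]]
  L <- n - q + 1L
  hit <- rep(TRUE, L)
  for (j in seq_len(q)) {
    hit <- hit & (chars[j:(j + L - 1L)] == binc[j])
  }
  as.integer(hit)
}

#' Causal FIR filter (convolution summation)
#'
#' Computes `y[n] = sum_{i=0..k} b[i] * x[n - i]` with zero initial
#' conditions (`x[m] = 0` for `m < 1`) and output truncated to
#' `length(x)`.  This is the sliding-window smoother that turns a binary
#' bin signature into a positional word-density profile; with unit
#' coefficients of width `W` it counts bin occurrences in the trailing
#' window of `W` signature positions.
#'
#' @param x Numeric input vector (non-empty, finite).
#' @param b Numeric filter coefficients `b[0] ... b[k]` (at least one
#'   tap, finite), or a `filter_coefficients` object.
#' @return Numeric vector of `length(x)`.
#' @examples
#' fir_filter(c(1, 1, 0, 0, 0, 0), c(0.2, 0.1, 0.3, 0.4))
#' # 0.2 0.3 0.4 0.7 0.4 0.0
#' @export
fir_filter <- function(x, b) {
  if (inherits(b, "filter_coefficients")) b <- b$b
  x <- as.numeric(x)
  b <- as.numeric(b)
  if (length(x) == 0L) stop("empty input signal", call. = FALSE)
  if (length(b) == 0L) stop("filter needs at least one tap", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  if (!all(is.finite(b))) stop("non-finite filter coefficients", call. = FALSE)
  n <- length(x)
  y <- numeric(n)
  for (i in seq_along(b)) {        # tap i has lag i - 1
    lag <- i - 1L
    if (lag < n) {
      y[(lag + 1L):n] <- y[(lag + 1L):n] + b[i] * x[1:(n - lag)]
    }
  }
  y
}

#' Uniform sliding-window filter coefficients
#'
#' The default window of the density pipeline: `W` taps, each 1 (so the
#' filtered signature is an integer occurrence count in `[0, W]`) or
#' each `1/W` when `normalize = TRUE` (densities in `[0, 1]`).
#'
#' @param W Window width in signature positions (positive integer).
#' @param normalize If `TRUE`, scale taps to sum to 1.
#' @return A `filter_coefficients` object: list with numeric `b` and
#'   filter order `k = W - 1`.
#' @export
uniform_window <- function(W, normalize = FALSE) {
  if (length(W) != 1L || is.na(W) || W != as.integer(W) || W < 1) {
    stop("window width W must be a positive integer", call. = FALSE)
  }
  W <- as.integer(W)
  b <- rep(if (normalize) 1 / W else 1, W)
  filter_coefficients(b)
}

#' @rdname uniform_window
#' @param b Numeric vector of filter weights `b[0] ... b[k]`.
#' @export
filter_coefficients <- function(b) {
  b <- as.numeric(b)
  if (length(b) < 1L) stop("filter needs at least one tap", call. = FALSE)
  if (!all(is.finite(b))) stop("non-finite filter coefficients", call. = FALSE)
  structure(list(b = b, k = length(b) - 1L), class = "filter_coefficients")
}

#' Word-density profile of one sequence
#'
#' For every bin of the q-gram alphabet, in lexicographic order, the
#' bin signature of `seq` is passed through the causal FIR filter `b`.
#' The result is the `4^q` by `nchar(seq) - q + 1` matrix of local word
#' densities along the sequence.
#'
#' Internally all `4^q` signatures are derived in one pass by base-4
#' encoding each window; positions whose window touches an `N` match no
#' bin.  The per-bin rows equal `fir_filter(bin_signature(seq, bin), b)`.
#'
#' @param seq DNA string (or a single-record `seq_set` element).
#' @param q Word length.
#' @param b Filter coefficients (vector or `filter_coefficients`).
#' @param id Optional sequence id stored with the profile.
#' @return A `density_profile`: list with `seq_id`, `q`, `bins`, and the
#'   numeric matrix `rows` (bins x positions, dimnames set).
#' @examples
#' p <- density_profile("AACTCG", q = 1, b = c(0.2, 0.1, 0.3, 0.4))
#' p$rows["A", ]  # 0.2 0.3 0.4 0.7 0.4 0.0
#' @export
density_profile <- function(seq, q, b, id = "seq") {
  if (inherits(b, "filter_coefficients")) b <- b$b
  alphabet <- enumerate_bins(q)
  n <- nchar(seq)
  if (n < q) {
    stop("sequence length (", n, ") is below the word length q = ", q,
         call. = FALSE)
  }
  L <- n - q + 1L
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T")) - 1L   # N and friends -> NA
  # base-4 index of the q-gram starting at each position (NA if any N)
  idx <- integer(L)
  idx[] <- 0L
  ok <- rep(TRUE, L)
  for (j in seq_len(q)) {
    cj <- code[j:(j + L - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 0L
    idx <- idx * 4L + cj
  }
  nb <- length(alphabet$bins)
  rows <- matrix(0, nrow = nb, ncol = L,
                 dimnames = list(alphabet$bins, NULL))
  hits <- which(ok)
  if (length(hits)) {
    sig <- matrix(0L, nrow = nb, ncol = L)
    sig[cbind(idx[hits] + 1L, hits)] <- 1L
    for (r in seq_len(nb)) rows[r, ] <- fir_filter(sig[r, ], b)
  }
  structure(list(seq_id = id, q = alphabet$q, bins = alphabet$bins,
                 rows = rows),
            class = "density_profile")
}

#' Density profiles for every record of a sequence set
#'
#' @param x A `seq_set`.
#' @inheritParams density_profile
#' @return List of `density_profile`, one per record, in file order.
#' @export
density_profiles <- function(x, q, b) {
  stopifnot(inherits(x, "seq_set"))
  lapply(x$ids, function(id) density_profile(x$seqs[[id]], q, b, id = id))
}
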