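#' Canonicalize a k-mer
#'
#' A canonical k-mer is the lexicographically smaller of a DNA word and its
#' reverse complement. Canonical form gives every k-mer a strand-free
#' identity, which is what the de Bruijn graph stores. Only odd `k` is
#' allowed so that no word can be its own reverse complement.
#'
#' @param word A DNA string over A, C, G, T (lowercase tolerated). Length
#'   must be odd.
#' @return A list with `kmer` (the canonical word) and `strand` (`"+"` if
#'   `word` was already canonical, `"-"` if its reverse complement is).
#' @examples
#' canonical_kmer("CGT")  # canonical form is ACG, input was the "-" strand
#' @export
canonical_kmer <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) %% 2L == 0L) {
    stop("k must be odd (even-length words can be their own reverse complement)")
  }
  cpp_canonical_kmer(word)
}

#' Reverse complement of a DNA string
#'
#' @param x A character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Extract canonical k-mers from a sequence
#'
#' Slides a window of width `k` along the sequence and reports one row per
#' window made only of A, C, G, T. Windows containing any other symbol
#' (ambiguity codes, N) are skipped; for a clean sequence of length L the
#' result has exactly L - k + 1 rows.
#'
#' @param sequence A single DNA string; lowercase and ambiguity codes
#'   tolerated (ambiguous windows are dropped).
#' @param k Odd k-mer length (default 31).
#' @return A tibble with columns `kmer` (canonical), `strand` (`"+"` when
#'   the window itself was canonical) and `offset` (0-based window start).
#' @export
extract_kmers <- function(sequence, k = 31L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  as_tibble(cpp_extract_kmers(sequence, k))
}
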