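#' Minimizer sketching parameters
#'
#' Bundles the three parameters of minimum sparse hashing (winnowing): the
#' k-mer length `k`, the window size `w` (number of consecutive k-mers per
#' window), and the integer `seed` of the 64-bit hash used to rank k-mers.
#' Identical `(k, w, seed)` on identical input always yields identical
#' sketches.
#'
#' The defaults `k = 30`, `w = 40` follow the tuning regime in which raising
#' k from 20 to 30 at w = 40 improves both accuracy and precision of read
#' cloud deconvolution.
#'
#' @param k k-mer length in bases (>= 1).
#' @param w window size in consecutive k-mers (>= 1).
#' @param seed integer seed of the hash function.
#' @return An object of class `hash_params`.
#' @examples
#' hash_params(k = 5, w = 3, seed = 1)
#' @export
hash_params <- function(k = 30L, w = 40L, seed = 42L) {
  k <- as.integer(k); w <- as.integer(w); seed <- as.integer(seed)
  stopifnot(length(k) == 1L, length(w) == 1L, length(seed) == 1L,
            !is.na(k), !is.na(w), !is.na(seed), k >= 1L, w >= 1L)
  structure(list(k = k, w = w, seed = seed), class = "hash_params")
}

#' @export
print.hash_params <- function(x, ...) {
  cat(sprintf("hash_params: k=%d w=%d seed=%d (overlap guarantee: %d bases)\n",
              x$k, x$w, x$seed, x$w + x$k - 1L))
  invisible(x)
}

#' Minimizer (minimum sparse k-mer) sketch of a DNA sequence
#'
#' Slides a window of `w` consecutive k-mers along the sequence and keeps, per
#' window, the k-mer with the smallest seeded 64-bit hash (ties broken toward
#' the leftmost position). The sketch is the unique set of selected k-mers.
#' Any two sequences with an exact overlap of at least `w + k - 1` bases are
#' guaranteed to share at least one minimizer.
#'
#' K-mers are canonicalized to the lexicographic minimum of the k-mer and its
#' reverse complement before hashing, so sketches are strand-symmetric.
#' K-mers containing `N` are skipped and windows are formed over the valid
#' k-mers only.
#'
#' @param sequence a single DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param params a [hash_params()] object.
#' @return Character vector of canonical k-mer tokens (sorted). Sequences
#'   shorter than `k + w - 1` yield an empty sketch carrying attribute
#'   `too_short = TRUE`; non-DNA characters are an error.
#' @examples
#' minimizer_set("ACGTACGTACGT", hash_params(k = 4, w = 3, seed = 1))
#' @export
minimizer_set <- function(sequence, params = hash_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) < params$k + params$w - 1L) {
    return(structure(character(0), too_short = TRUE))
  }
  minimizer_set_cpp(sequence, params$k, params$w, params$seed)
}

#' Joint sketch of a read pair
#'
#' Paired-end mates necessarily derive from the same DNA fragment, so they
#' are sketched as one logical read: the union of the two mates' minimizer
#' sets. Either mate may be `NA` or empty (single-end data).
#'
#' @param read1,read2 DNA strings (either may be `NA` or `""`).
#' @inheritParams minimizer_set
#' @return Character vector of canonical k-mer tokens; empty when both mates
#'   are too short to sketch.
#' @export
sketch_read_pair <- function(read1, read2 = NA_character_, params = hash_params()) {
  s1 <- if (is.na(read1)) character(0) else minimizer_set(read1, params)
  s2 <- if (is.na(read2)) character(0) else minimizer_set(read2, params)
  sort(unique(c(s1, s2)))
}

#' Canonical form of k-mers
#'
#' Lexicographic minimum of each k-mer and its reverse complement — the
#' strand-symmetric token identity used throughout.
#'
#' @param kmers character vector of DNA k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  canonical_kmers_cpp(toupper(kmers))
}

#' Seeded 64-bit hash of k-mer strings
#'
#' The ranking hash used for minimizer selection, exposed for inspection and
#' for independent re-derivations of the windowing. Returned as fixed-width
#' hexadecimal so that lexicographic order equals numeric order exactly.
#'
#' @param kmers character vector of k-mer strings (hashed literally, no
#'   canonicalization).
#' @param seed integer hash seed.
#' @return Character vector of 16-digit hex hashes.
#' @export
hash_kmer <- function(kmers, seed = 42L) {
  hash_kmers_cpp(kmers, as.integer(seed))
}
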