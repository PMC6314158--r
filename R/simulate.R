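#' Synthetic metagenomic community
#'
#' Generates `n_genomes` i.i.d. uniform random genome sequences with
#' geometrically decaying abundances `P(G_i) proportional to 2^-i`, the
#' skewed regime typical of microbial communities (1-2 dominant species with
#' a long tail).
#'
#' @param n_genomes number of genomes.
#' @param genome_length length of each genome in bases.
#' @param seed integer RNG seed.
#' @return A `synthetic_community` object: list with `genomes` (named
#'   character vector of sequences) and `abundances` (named probability
#'   vector summing to 1).
#' @export
make_community <- function(n_genomes = 5L, genome_length = 1e6, seed = 1L) {
  stopifnot(n_genomes >= 1, genome_length >= 1)
  set.seed(seed)
  n_genomes <- as.integer(n_genomes)
  genome_length <- as.integer(genome_length)
  ids <- sprintf("genome%02d", seq_len(n_genomes))
  genomes <- vapply(ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
          collapse = "")
  }, character(1))
  ab <- 2^(-seq_len(n_genomes))
  ab <- ab / sum(ab)
  names(ab) <- ids
  structure(list(genomes = genomes, abundances = ab),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("synthetic_community: %d genomes of %s bases; abundances %s\n",
              length(x$genomes),
              format(nchar(x$genomes[[1]]), big.mark = ","),
              paste(signif(x$abundances, 3), collapse = ", ")))
  invisible(x)
}

# lambda of a zero-truncated Poisson whose mean equals target
ztp_lambda <- function(target) {
  if (target <= 1) stop("nf_mean must be > 1 for a zero-truncated Poisson",
                        call. = FALSE)
  stats::uniroot(function(l) l / (1 - exp(-l)) - target,
                 interval = c(1e-8, target), tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(z <- x == 0L)) x[z] <- stats::rpois(sum(z), lambda)
  x
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(1L, sum(lens), error_rate)
  if (n_err == 0L) return(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  pos <- sample.int(sum(lens), n_err)
  rd <- findInterval(pos, offs + 1L)
  within <- pos - offs[rd]
  shift <- sample.int(3L, n_err, replace = TRUE)  # 1..3 bases away, cyclic
  bases <- c("A", "C", "G", "T")
  for (g in split(seq_len(n_err), rd)) {
    i <- rd[g[1L]]
    s <- strsplit(seqs[i], "")[[1L]]
    p <- within[g]
    cur <- match(s[p], bases)
    s[p] <- bases[((cur - 1L + shift[g]) %% 4L) + 1L]
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate barcoded linked reads with ground truth
#'
#' Emulates linked-read (read cloud) sequencing of a synthetic community
#' under the generative model: each barcode receives `N_f` long fragments
#' (genome drawn by geometric abundance, start uniform within the genome),
#' and each fragment is sparsely covered by paired-end reads at an expected
#' fractional coverage `C_r`. Mates are placed at a fixed insert size, the
#' pair's strand is chosen uniformly, and i.i.d. substitution errors are
#' applied.
#'
#' `N_f` per barcode is drawn from a zero-truncated Poisson calibrated so
#' that its mean equals `nf_mean` exactly (set `nf_constant = TRUE` for a
#' fixed `N_f`). Barcodes are unique random 16-base strings, so barcode
#' collisions never occur by construction.
#'
#' @param community a [make_community()] object.
#' @param n_barcodes number of read clouds to generate.
#' @param nf_mean mean number of fragments per barcode (> 1 unless
#'   `nf_constant`).
#' @param fragment_length fragment length in bases.
#' @param C_r expected fractional coverage of each fragment by reads.
#' @param read_length read (mate) length in bases.
#' @param insert_size outer distance between mate starts' span (>=
#'   `2 * read_length`).
#' @param error_rate per-base substitution error rate.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param nf_constant if `TRUE`, every barcode gets exactly
#'   `round(nf_mean)` fragments.
#' @param fastq optional path: write the reads as interleaved BX-tagged
#'   FASTQ.
#' @param truth_path optional path: write the truth table as TSV.
#' @return List with `reads` (data.table: `read_id`, `barcode`, `seq1`,
#'   `seq2`) and `truth` (data.table: `read_id`, `barcode`, `genome_id`,
#'   `fragment_id`, `fragment_start`, `fragment_end`; one row per read
#'   pair).
#' @export
simulate_linked_reads <- function(community, n_barcodes = 2000L,
                                  nf_mean = 3, fragment_length = 10000L,
                                  C_r = 0.5, read_length = 100L,
                                  insert_size = 300L, error_rate = 0.001,
                                  seed = 1L, nf_constant = FALSE,
                                  fastq = NULL, truth_path = NULL) {
  stopifnot(inherits(community, "synthetic_community"),
            n_barcodes >= 1, fragment_length >= read_length,
            insert_size >= 2 * read_length, C_r > 0, C_r <= 1,
            error_rate >= 0, error_rate < 1)
  glen <- nchar(community$genomes[[1L]])
  if (fragment_length > glen)
    stop("fragment_length exceeds genome length", call. = FALSE)
  set.seed(seed)
  n_barcodes <- as.integer(n_barcodes)
  fragment_length <- as.integer(fragment_length)
  read_length <- as.integer(read_length)
  insert_size <- as.integer(insert_size)

  barcodes <- replicate(n_barcodes, paste(
    sample(c("A", "C", "G", "T"), 16L, replace = TRUE), collapse = ""))
  while (anyDuplicated(barcodes)) {
    dup <- duplicated(barcodes)
    barcodes[dup] <- replicate(sum(dup), paste(
      sample(c("A", "C", "G", "T"), 16L, replace = TRUE), collapse = ""))
  }

  nf <- if (nf_constant) rep(as.integer(round(nf_mean)), n_barcodes)
        else rztpois(n_barcodes, ztp_lambda(nf_mean))

  n_frag <- sum(nf)
  frag <- data.table(
    barcode = rep(barcodes, nf),
    genome_id = sample(names(community$abundances), n_frag, replace = TRUE,
                       prob = community$abundances),
    fragment_start = sample.int(glen - fragment_length + 1L, n_frag,
                                replace = TRUE))
  frag[, fragment_id := sprintf("frag%06d", .I)]
  frag[, fragment_end := fragment_start + fragment_length - 1L]

  pairs_per_frag <- stats::rpois(
    n_frag, C_r * fragment_length / (2 * read_length))
  fr <- frag[rep(seq_len(n_frag), pairs_per_frag)]
  n_pairs <- nrow(fr)
  if (n_pairs == 0L) stop("no reads generated; increase C_r or sizes",
                          call. = FALSE)
  s <- sample.int(fragment_length - insert_size + 1L, n_pairs,
                  replace = TRUE) - 1L
  gstart <- fr$fragment_start + s
  m1 <- substring(community$genomes[fr$genome_id], gstart,
                  gstart + read_length - 1L)
  m2 <- revcomp_chr(substring(community$genomes[fr$genome_id],
                              gstart + insert_size - read_length,
                              gstart + insert_size - 1L))
  flip <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  seq1 <- ifelse(flip, revcomp_chr(m2), m1)
  seq2 <- ifelse(flip, revcomp_chr(m1), m2)
  seq1 <- apply_substitution_errors(seq1, error_rate)
  seq2 <- apply_substitution_errors(seq2, error_rate)

  reads <- data.table(read_id = sprintf("read%08d", seq_len(n_pairs)),
                      barcode = fr$barcode, seq1 = seq1, seq2 = seq2)
  truth <- data.table(read_id = reads$read_id, barcode = fr$barcode,
                      genome_id = fr$genome_id, fragment_id = fr$fragment_id,
                      fragment_start = fr$fragment_start,
                      fragment_end = fr$fragment_end)
  setkey(reads, read_id)
  setkey(truth, read_id)

  if (!is.null(fastq)) write_linked_fastq(reads, fastq)
  if (!is.null(truth_path)) fwrite(truth, truth_path, sep = "\t")
  list(reads = reads[], truth = truth[])
}

#' Write reads as interleaved BX-tagged FASTQ
#'
#' Mates share a read id and carry the barcode as a `BX:Z:` comment tag;
#' qualities are uniform. [load_clouds()] round-trips this format.
#'
#' @param reads data.table with `read_id`, `barcode`, `seq1`, `seq2`.
#' @param path output FASTQ path (`.gz` for compressed output).
#' @return The path, invisibly.
#' @export
write_linked_fastq <- function(reads, path) {
  paired <- !is.na(reads$seq2)
  hdr <- paste0(reads$read_id, " BX:Z:", reads$barcode)
  ord <- rep(seq_len(nrow(reads)), 1L + paired)          # interleave mates
  second <- sequence(1L + paired) == 2L
  seqs <- ifelse(second, reads$seq2[ord], reads$seq1[ord])
  hdrs <- hdr[ord]
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- hdrs
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a truth table written by the simulator
#'
#' @param path TSV path.
#' @return data.table keyed by `read_id`.
#' @export
read_truth <- function(path) {
  tt <- fread(path, sep = "\t")
  setkey(tt, read_id)
  tt[]
}
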