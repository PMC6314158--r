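#' @import data.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib linkclouds, .registration = TRUE
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  "read_id", "barcode", "token", "seq1", "seq2", "count", "retained",
  "n_reads", "shared", "degree", "cluster", "r1", "r2", "weight",
  "genome_id", "fragment_id", "class_id", "cloud_id", "group", "taxon_id",
  "header", "mate", "read_id.1", "read_id.2", "J", "N", ".",
  "parent_id", "name", "status", "promoted", "original_taxon_id",
  "from_rank", "to_rank", "V1", "V2", "V3", "shannon",
  "fragment_start", "fragment_end", ".I", ".N", ".SD"
))

barcode_from_header <- function(headers) {
  # BX:Z: comment tag (10x convention), else a trailing /BX:<code> suffix
  bx <- rep(NA_character_, length(headers))
  m <- regmatches(headers, regexpr("BX:Z:[^[:space:]]+", headers))
  has <- grepl("BX:Z:", headers)
  bx[has] <- sub("^BX:Z:", "", m)
  alt <- !has & grepl("/BX:[^[:space:]/]+", headers)
  if (any(alt)) {
    ma <- regmatches(headers[alt], regexpr("/BX:[^[:space:]/]+", headers[alt]))
    bx[alt] <- sub("^/BX:", "", ma)
  }
  bx
}

# structural check with record numbers; Biostrings tolerates some truncation
validate_fastq <- function(fp) {
  con <- gzfile(fp, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in '", fp, "': line count not a multiple of 4 ",
         "(truncated record ", length(lines) %/% 4L + 1L, ")", call. = FALSE)
  heads <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ in '", fp, "': record ", bad[1L],
         " lacks @/+ markers", call. = FALSE)
  invisible(TRUE)
}

read_id_from_header <- function(headers) {
  id <- sub("[[:space:]].*$", "", headers)
  id <- sub("/BX:[^/]*$", "", id)
  sub("/[12]$", "", id)
}

#' Load barcoded FASTQ files into a read cloud set
#'
#' Parses one or more (optionally gzipped) FASTQ files of barcoded short
#' reads, groups reads by their exact 3' barcode into read clouds, merges
#' mates sharing a read id into one logical paired read, and sketches every
#' read with minimizer k-mers. Barcodes are taken from a `BX:Z:` comment tag
#' or from a trailing `/BX:<code>` header suffix; reads lacking a barcode are
#' counted and discarded.
#'
#' @param fastq_paths character vector of FASTQ file paths.
#' @param params a [hash_params()] object used to sketch the reads.
#' @param verbose emit a summary line to stderr.
#' @return A `cloud_set` object: list with elements `reads` (data.table:
#'   `read_id`, `barcode`, `seq1`, `seq2`), `tokens` (data.table: `read_id`,
#'   `barcode`, `token`; one row per distinct token per read), `params`, and
#'   `n_unbarcoded` (count of discarded records).
#' @export
load_clouds <- function(fastq_paths, params = hash_params(), verbose = TRUE) {
  stopifnot(length(fastq_paths) >= 1L, all(file.exists(fastq_paths)))
  recs <- lapply(fastq_paths, function(fp) {
    validate_fastq(fp)
    x <- tryCatch(
      Biostrings::readDNAStringSet(fp, format = "fastq"),
      error = function(e) stop("malformed FASTQ in '", fp, "': ",
                               conditionMessage(e), call. = FALSE))
    data.table(header = names(x), seq = as.character(x))
  })
  recs <- rbindlist(recs)
  recs[, barcode := barcode_from_header(header)]
  n_unbarcoded <- sum(is.na(recs$barcode))
  recs <- recs[!is.na(barcode)]
  if (nrow(recs) == 0L)
    stop("no barcoded reads found in input", call. = FALSE)
  recs[, read_id := read_id_from_header(header)]
  # merge mates: first record of an id is mate 1, second is mate 2
  recs[, mate := seq_len(.N), by = read_id]
  if (any(recs$mate > 2L))
    stop("more than two FASTQ records share a read id (first offender: ",
         recs[mate > 2L][1L, read_id], ")", call. = FALSE)
  reads <- dcast(recs, read_id + barcode ~ mate, value.var = "seq")
  setnames(reads, "1", "seq1")
  if ("2" %in% names(reads)) setnames(reads, "2", "seq2")
  else reads[, seq2 := NA_character_]
  setkey(reads, barcode, read_id)
  cs <- cloud_set_from_reads(reads, params)
  cs$n_unbarcoded <- n_unbarcoded
  if (verbose)
    message(sprintf("loaded %d reads (%d unbarcoded discarded) in %d clouds",
                    nrow(reads), n_unbarcoded, uniqueN(reads$barcode)))
  cs
}

#' Build a read cloud set from an in-memory read table
#'
#' Same container as [load_clouds()] builds, but from a data.frame of reads
#' (as produced by [simulate_linked_reads()]) rather than a FASTQ file.
#'
#' @param reads data.frame/data.table with columns `read_id`, `barcode`,
#'   `seq1` and optionally `seq2`.
#' @param params a [hash_params()] object.
#' @return A `cloud_set` object.
#' @export
cloud_set_from_reads <- function(reads, params = hash_params()) {
  reads <- as.data.table(reads)
  stopifnot(all(c("read_id", "barcode", "seq1") %in% names(reads)),
            !anyNA(reads$barcode), all(nzchar(reads$barcode)))
  if (anyDuplicated(reads$read_id))
    stop("read ids must be unique within the dataset", call. = FALSE)
  if (!"seq2" %in% names(reads)) reads[, seq2 := NA_character_]
  reads <- reads[, .(read_id, barcode, seq1, seq2)]
  setkey(reads, barcode, read_id)
  sk <- sketch_pairs_cpp(reads$seq1, reads$seq2,
                         params$k, params$w, params$seed)
  nt <- lengths(sk)
  tokens <- data.table(
    read_id = rep(reads$read_id, nt),
    barcode = rep(reads$barcode, nt),
    token   = unlist(sk, use.names = FALSE))
  setkey(tokens, token)
  structure(list(reads = reads, tokens = tokens, params = params,
                 n_unbarcoded = 0L),
            class = "cloud_set")
}

#' @export
print.cloud_set <- function(x, ...) {
  cat(sprintf(
    "cloud_set: %d reads in %d clouds; %d token occurrences (%d distinct); k=%d w=%d\n",
    nrow(x$reads), uniqueN(x$reads$barcode), nrow(x$tokens),
    uniqueN(x$tokens$token), x$params$k, x$params$w))
  invisible(x)
}

#' Read cloud sizes
#'
#' @param cs a `cloud_set`.
#' @return data.table with columns `barcode`, `n_reads`.
#' @export
cloud_sizes <- function(cs) {
  cs$reads[, .(n_reads = .N), by = barcode]
}

#' Drop read clouds below a minimum size
#'
#' Clouds with fewer than `dropout` reads are removed entirely (they neither
#' serve as anchors nor as foreign clouds). The default of 2 reflects that a
#' cloud of one read is trivially deconvolved and size-1 groups are excluded
#' from all results.
#'
#' @param cs a `cloud_set`.
#' @param dropout minimum number of reads for a cloud to be kept.
#' @return A filtered `cloud_set`.
#' @export
drop_small_clouds <- function(cs, dropout = 2L) {
  stopifnot(inherits(cs, "cloud_set"), dropout >= 0)
  keep <- cloud_sizes(cs)[n_reads >= dropout, barcode]
  out <- cs
  out$reads <- cs$reads[barcode %in% keep]
  out$tokens <- cs$tokens[barcode %in% keep]
  setkey(out$reads, barcode, read_id)
  setkey(out$tokens, token)
  out
}

#' Build the global minimizer vocabulary
#'
#' Counts, for every distinct minimizer token, the number of reads
#' (dataset-wide) whose sketch contains it; a token occurring twice in one
#' read counts once. The arithmetic mean count over all distinct tokens is
#' recorded for the stop-word filter.
#'
#' @param cs a `cloud_set`.
#' @return A `vocabulary` object: list with `counts` (data.table: `token`,
#'   `count`), `mean_count`, and `retained` (character vector, `NULL` until
#'   [filter_vocabulary()] is applied).
#' @export
build_vocabulary <- function(cs) {
  stopifnot(inherits(cs, "cloud_set"))
  counts <- cs$tokens[, .(count = .N), by = token]
  setkey(counts, token)
  structure(list(counts = counts,
                 mean_count = mean(counts$count),
                 retained = NULL),
            class = "vocabulary")
}

#' Filter the vocabulary (singleton and stop-word removal)
#'
#' Tokens that occur exactly once cannot link two read clouds and are
#' discarded; tokens occurring many times more than the average (10 times
#' more, by default) tend to come from low-complexity or conserved sequence
#' and create false positives, so they are discarded too. The mean is the one
#' computed by [build_vocabulary()], i.e. before any removal.
#'
#' @param vocab a `vocabulary` from [build_vocabulary()].
#' @param max_multiple stop-word cutoff as a multiple of the mean count.
#' @return The vocabulary with `retained` filled in.
#' @export
filter_vocabulary <- function(vocab, max_multiple = 10) {
  stopifnot(inherits(vocab, "vocabulary"), max_multiple > 0)
  cutoff <- max_multiple * vocab$mean_count
  vocab$retained <- vocab$counts[count >= 2L & count <= cutoff, token]
  vocab
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("vocabulary: %d distinct tokens, mean count %.3f%s\n",
              nrow(x$counts), x$mean_count,
              if (is.null(x$retained)) " (unfiltered)"
              else sprintf(", %d retained", length(x$retained))))
  invisible(x)
}
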