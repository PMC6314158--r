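#' Truth-class composition of a read group
#'
#' Proportions of a cloud's member reads per fragment class, where a class
#' is the `(genome_id, fragment_id)` pair from the simulator truth table;
#' multiple fragments of one genome within one barcode count as distinct
#' classes.
#'
#' @param read_ids character vector of member read ids.
#' @param truth truth table (data.table with `read_id`, `genome_id`,
#'   `fragment_id`).
#' @return Named numeric vector of proportions (sums to 1), names are
#'   `genome_id:fragment_id`.
#' @export
composition <- function(read_ids, truth) {
  stopifnot(length(read_ids) >= 1L)
  hit <- truth[J(read_ids), on = "read_id"]
  if (anyNA(hit$genome_id)) {
    missing <- read_ids[is.na(hit$genome_id)][1L]
    stop("read id not present in truth table: ", missing, call. = FALSE)
  }
  tab <- table(paste(hit$genome_id, hit$fragment_id, sep = ":"))
  p <- as.numeric(tab) / length(read_ids)
  names(p) <- names(tab)
  p
}

#' Purity of a composition
#'
#' `P = max(p)`: the proportion of the dominant fragment class. A perfect
#' (single-fragment) cloud has `P = 1`.
#'
#' @param p composition vector from [composition()] (non-negative, sums
#'   to 1).
#' @return Scalar in (0, 1].
#' @export
purity <- function(p) {
  stopifnot(length(p) >= 1L, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  max(p)
}

#' Shannon index of a composition
#'
#' `H = -sum(p_i * ln p_i)` with `0 * ln 0 := 0`. A perfect cloud has
#' `H = 0`; for `m` classes the maximum `ln m` is reached at the uniform
#' composition. Reported non-negative (natural log).
#'
#' @inheritParams purity
#' @return Scalar >= 0.
#' @export
shannon_index <- function(p) {
  stopifnot(length(p) >= 1L, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  p <- p[p > 0]
  -sum(p * log(p))
}

score_groups <- function(groups, truth) {
  # groups: data.table (cloud_id, read_id)
  hit <- truth[groups, on = "read_id"]
  if (anyNA(hit$genome_id))
    stop("read id not present in truth table", call. = FALSE)
  hit[, class_id := paste(genome_id, fragment_id, sep = ":")]
  hit[, {
    tab <- tabulate(factor(class_id))
    p <- tab / sum(tab)
    .(n_reads = .N, purity = max(p),
      shannon = -sum(p[p > 0] * log(p[p > 0])))
  }, by = cloud_id]
}

#' Score enhanced and standard read clouds against truth
#'
#' Computes purity and Shannon index for every enhanced read cloud (clusters
#' of size >= 2; unassigned reads and size-1 clusters are excluded) and for
#' every standard (untouched 3' barcode) read cloud, and summarizes both
#' groups, including size-stratified means.
#'
#' @param deconv a `deconvolution` from [deconvolve_all()].
#' @param cs the `cloud_set` that was deconvolved.
#' @param truth simulator truth table.
#' @return List with `per_cloud` (data.table: `group` = enhanced/standard,
#'   `cloud_id`, `n_reads`, `purity`, `shannon`), `summary` (per-group mean
#'   and median purity and Shannon index, number of clouds, fraction
#'   perfect), and `by_size` (per-group, per-cloud-size mean scores).
#' @export
summarize_deconvolution <- function(deconv, cs, truth) {
  stopifnot(inherits(deconv, "deconvolution"), inherits(cs, "cloud_set"))
  enh <- deconv$assignments[cluster > 0L, .(cloud_id, read_id)]
  enh_sc <- if (nrow(enh)) score_groups(enh, truth) else
    data.table(cloud_id = character(0), n_reads = integer(0),
               purity = numeric(0), shannon = numeric(0))
  std <- cs$reads[, .(cloud_id = barcode, read_id)]
  std_sc <- score_groups(std, truth)
  per_cloud <- rbindlist(list(
    enh_sc[, c(.(group = "enhanced"), .SD)],
    std_sc[, c(.(group = "standard"), .SD)]))
  summary <- per_cloud[, .(
    n_clouds = .N,
    mean_purity = mean(purity), median_purity = stats::median(purity),
    mean_shannon = mean(shannon), median_shannon = stats::median(shannon),
    frac_perfect = mean(purity == 1),
    mean_size = mean(n_reads)), by = group]
  by_size <- per_cloud[, .(mean_purity = mean(purity),
                           mean_shannon = mean(shannon), n_clouds = .N),
                       by = .(group, n_reads)][order(group, n_reads)]
  list(per_cloud = per_cloud[], summary = summary[], by_size = by_size[])
}

#' Export read clouds as bag-of-minimizers documents
#'
#' Treats each (enhanced or standard) read cloud as a document whose words
#' are its retained minimizer tokens, in the spirit of bag-of-words topic
#' modelling; stop-word-like tokens have already been removed by
#' [filter_vocabulary()]. The result is a sparse document-term matrix
#' suitable for any external topic-model or clustering tool.
#'
#' @param cs a `cloud_set`.
#' @param vocab a filtered `vocabulary`.
#' @param assignments optional assignment table from [deconvolve_all()]
#'   (`read_id`, `cloud_id`); when supplied, documents are enhanced clouds
#'   (clusters of size >= 2), otherwise standard barcodes.
#' @return A `Matrix::sparseMatrix` (documents x tokens) with dimnames;
#'   documents with no retained tokens are kept as empty rows and listed in
#'   attribute `empty_documents`.
#' @export
export_documents <- function(cs, vocab, assignments = NULL) {
  stopifnot(inherits(cs, "cloud_set"), inherits(vocab, "vocabulary"))
  if (is.null(vocab$retained))
    stop("vocabulary has not been filtered", call. = FALSE)
  if (is.null(assignments)) {
    docs <- cs$reads[, .(read_id, cloud_id = barcode)]
  } else {
    a <- as.data.table(assignments)
    docs <- a[cluster > 0L, .(read_id, cloud_id)]
  }
  tok <- cs$tokens[token %chin% vocab$retained][docs, on = "read_id",
                                                nomatch = NULL]
  counts <- tok[, .(count = .N), by = .(cloud_id, token)]
  doc_ids <- sort(unique(docs$cloud_id))
  tok_ids <- sort(unique(vocab$retained))
  m <- Matrix::sparseMatrix(
    i = match(counts$cloud_id, doc_ids),
    j = match(counts$token, tok_ids),
    x = counts$count,
    dims = c(length(doc_ids), length(tok_ids)),
    dimnames = list(doc_ids, tok_ids))
  empty <- doc_ids[!(doc_ids %in% counts$cloud_id)]
  attr(m, "empty_documents") <- empty
  m
}

#' Write a document-term matrix as MTX with index files
#'
#' Writes `<prefix>.mtx` (MatrixMarket sparse counts), `<prefix>.documents.txt`
#' and `<prefix>.tokens.txt` (row and column names, one per line).
#'
#' @param m matrix from [export_documents()].
#' @param prefix output path prefix.
#' @return The `.mtx` path, invisibly.
#' @export
write_documents_mtx <- function(m, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(m, mtx)
  writeLines(rownames(m), paste0(prefix, ".documents.txt"))
  writeLines(colnames(m), paste0(prefix, ".tokens.txt"))
  invisible(mtx)
}
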