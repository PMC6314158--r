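#' Load a taxonomy tree
#'
#' Accepts either a 4-column TSV (`taxon_id`, `parent_id`, `rank`, `name`;
#' header optional) or an NCBI-style `nodes.dmp` (fields separated by
#' `\t|\t`; names are then taken from the ids). The root is the unique node
#' whose parent is itself, `0`, or empty.
#'
#' @param path taxonomy file path, or a data.frame with those 4 columns.
#' @return A `taxonomy` object: list with `nodes` (data.table keyed by
#'   `taxon_id`), `parent` (named character vector), `root` (taxon id).
#' @export
read_taxonomy <- function(path) {
  if (is.data.frame(path)) {
    nodes <- as.data.table(path)
    setnames(nodes, seq_len(4L), c("taxon_id", "parent_id", "rank", "name"))
  } else {
    first <- readLines(path, n = 1L)
    if (grepl("\t\\|\t|\\|$", first)) {   # nodes.dmp dialect
      raw <- fread(path, sep = "|", header = FALSE, strip.white = TRUE,
                   fill = TRUE)
      nodes <- raw[, .(taxon_id = as.character(trimws(V1)),
                       parent_id = as.character(trimws(V2)),
                       rank = trimws(V3))]
      nodes[, name := taxon_id]
    } else {
      nodes <- fread(path, sep = "\t", header = grepl("taxon", first),
                     colClasses = "character")
      setnames(nodes, seq_len(4L), c("taxon_id", "parent_id", "rank", "name"))
    }
  }
  nodes[, `:=`(taxon_id = as.character(taxon_id),
               parent_id = as.character(parent_id))]
  is_root <- nodes$parent_id == nodes$taxon_id | nodes$parent_id %in%
    c("", "0", NA_character_)
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root", call. = FALSE)
  root <- nodes$taxon_id[is_root]
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  parent[root] <- NA_character_
  # verify acyclicity by walking every node to the root
  for (t in nodes$taxon_id) {
    seen <- character(0)
    while (!is.na(t)) {
      if (t %in% seen) stop("taxonomy contains a cycle at ", t, call. = FALSE)
      seen <- c(seen, t)
      t <- parent[[t]]
    }
  }
  setkey(nodes, taxon_id)
  structure(list(nodes = nodes[], parent = parent, root = root),
            class = "taxonomy")
}

root_path <- function(tree, taxon) {
  out <- character(0)
  t <- taxon
  while (!is.na(t)) {
    out <- c(out, t)
    t <- tree$parent[[t]]
  }
  out
}

#' Is taxon `a` a proper ancestor of taxon `b`?
#'
#' @param tree a `taxonomy` from [read_taxonomy()].
#' @param a,b taxon ids.
#' @return Logical: `TRUE` iff `a != b` and `a` lies on the root path of
#'   `b`.
#' @export
is_ancestor <- function(tree, a, b) {
  stopifnot(inherits(tree, "taxonomy"))
  if (!a %in% names(tree$parent)) stop("unknown taxon: ", a, call. = FALSE)
  if (!b %in% names(tree$parent)) stop("unknown taxon: ", b, call. = FALSE)
  if (a == b) return(FALSE)
  a %in% root_path(tree, b)[-1L]
}

#' Promote unspecific assignments within one read cloud
#'
#' All reads of one fragment share a taxon, so a read assigned to a high
#' (unspecific) taxon can be promoted to a lower one supported by other
#' reads in the same cloud. For a read at taxon `t`, the assigned taxa of
#' the cloud that are proper descendants of `t` are collected; if their
#' most-specific elements reduce to exactly one taxon, the read is
#' reassigned to it. Two or more incomparable most-specific descendants are
#' a conflict and the read is left unchanged. Unclassified reads (sentinel
#' `"unclassified"` or `"0"`) are never promoted. Promotions are computed
#' from the original assignments in a single pass and applied atomically
#' (no cascading).
#'
#' @param assignments data.table/data.frame with `read_id`, `taxon_id` for
#'   the reads of one cloud.
#' @param tree a `taxonomy`.
#' @return List with `assignments` (same rows, promoted `taxon_id`,
#'   `original_taxon_id`, logical `promoted`) and `n_promoted`.
#' @export
promote_cloud <- function(assignments, tree) {
  a <- as.data.table(assignments)[, .(read_id, taxon_id)]
  uncl <- c("unclassified", "0", "U", NA_character_)
  known <- setdiff(unique(a$taxon_id), uncl)
  bad <- setdiff(known, names(tree$parent))
  if (length(bad))
    stop("assignment references unknown taxon: ", bad[1L], call. = FALSE)
  # root paths once per distinct taxon present
  paths <- lapply(stats::setNames(known, known), root_path, tree = tree)
  depth <- lengths(paths)
  new_tax <- a$taxon_id
  for (i in seq_len(nrow(a))) {
    t <- a$taxon_id[i]
    if (t %in% uncl) next
    others <- known
    # proper descendants of t among taxa assigned in this cloud
    desc <- others[vapply(others, function(d)
      d != t && t %in% paths[[d]][-1L], logical(1))]
    if (length(desc) == 0L) next
    # most-specific elements: descendants that are not ancestors of another
    leaf <- desc[vapply(desc, function(d)
      !any(vapply(desc, function(e) e != d && d %in% paths[[e]][-1L],
                  logical(1))), logical(1))]
    if (length(leaf) == 1L) new_tax[i] <- leaf
  }
  out <- data.table(read_id = a$read_id, taxon_id = new_tax,
                    original_taxon_id = a$taxon_id,
                    promoted = new_tax != a$taxon_id)
  list(assignments = out[], n_promoted = sum(out$promoted))
}

#' Promote assignments across a set of read clouds
#'
#' Applies [promote_cloud()] within each group of a cloud map — standard 3'
#' barcodes or enhanced read clouds from [deconvolve_all()] — and summarizes
#' promotions by (from-rank, to-rank). Grouping by enhanced clouds reduces
#' the chance of conflicting taxa within a group and therefore rescues at
#' least as many reads, correctly, as grouping by raw barcodes.
#'
#' @param assignments data.table/data.frame with `read_id`, `taxon_id`.
#' @param cloud_map data.table/data.frame with `read_id`, `cloud_id`; must
#'   assign each read to at most one group.
#' @param tree a `taxonomy`.
#' @return List with `assignments` (promoted table over all mapped reads)
#'   and `summary` (data.table: `from_rank`, `to_rank`, `n`).
#' @export
promote_all <- function(assignments, cloud_map, tree) {
  a <- as.data.table(assignments)
  cm <- as.data.table(cloud_map)
  if (anyDuplicated(cm$read_id))
    stop("a read appears in two groups of the cloud map", call. = FALSE)
  merged <- a[cm, on = "read_id", nomatch = NULL]
  parts <- lapply(split(merged, by = "cloud_id"), promote_cloud, tree = tree)
  out <- rbindlist(lapply(parts, `[[`, "assignments"))
  rank_of <- stats::setNames(tree$nodes$rank, tree$nodes$taxon_id)
  prom <- out[promoted == TRUE]
  summary <- if (nrow(prom))
    prom[, .(n = .N), by = .(from_rank = rank_of[original_taxon_id],
                             to_rank = rank_of[taxon_id])][order(-n)]
  else data.table(from_rank = character(0), to_rank = character(0),
                  n = integer(0))
  setkey(out, read_id)
  list(assignments = out[], summary = summary[])
}

#' Read a Kraken-style classification table
#'
#' Five columns: status (`C`/`U`), read id, taxon id, length, k-mer string;
#' the last two are ignored. Unclassified reads get the sentinel
#' `"unclassified"`.
#'
#' @param path TSV path.
#' @return data.table with `read_id`, `taxon_id`, `status`.
#' @export
read_kraken <- function(path) {
  k <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
             fill = TRUE)
  out <- data.table(status = k$V1, read_id = k$V2, taxon_id = k$V3)
  out[status == "U", taxon_id := "unclassified"]
  setkey(out, read_id)
  out[]
}
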