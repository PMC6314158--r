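#' Deconvolution parameters
#'
#' Tuning knobs for the graph-based barcode deconvolution. These trade mean
#' enhanced-cloud purity against mean enhanced-cloud size:
#'
#' * `eps` — minimum number of shared foreign clouds for two anchor reads to
#'   be linked in the read-read graph (the DBSCAN-like density threshold).
#' * `maxk` — maximum number of foreign clouds one read may match; reads
#'   above it are too unspecific (repetitive/conserved sequence) and are
#'   removed from the bipartite graph.
#' * `min_shared`, `max_shared` — bounds on the number of retained tokens an
#'   anchor may share with a foreign cloud for the pair to be compared at
#'   all. Too few shared tokens is uninformative; too many indicates
#'   repetitive or conserved sequence rather than a real fragment overlap
#'   (overlaps far above the `C_r^2` expectation; see
#'   [expected_overlap_points()]). `max_shared = NA` derives the bound per
#'   anchor as `max(0.5 * anchor sketch size, min_shared)`.
#' * `max_cloud_degree` — maximum number of anchor reads a foreign-cloud node
#'   may touch before being discarded; `Inf` disables the filter.
#' * `anchor_dropout` — minimum cloud size for a cloud to be deconvolved as
#'   an anchor (smaller clouds still serve as foreign clouds).
#'
#' All defaults are artifact choices, exposed so they can be tuned per
#' dataset.
#'
#' @param eps minimum shared foreign clouds per read-read edge.
#' @param maxk maximum foreign-cloud matches per read.
#' @param min_shared minimum shared retained tokens between anchor and a
#'   candidate foreign cloud.
#' @param max_shared maximum shared retained tokens; `NA` = derived per
#'   anchor (see above).
#' @param max_cloud_degree maximum anchor reads per foreign-cloud node.
#' @param anchor_dropout minimum cloud size to be deconvolved.
#' @return An object of class `deconv_params`.
#' @export
deconv_params <- function(eps = 3L, maxk = 8L, min_shared = 3L,
                          max_shared = NA, max_cloud_degree = Inf,
                          anchor_dropout = 10L) {
  stopifnot(eps >= 1, maxk >= 1, min_shared >= 1,
            is.na(max_shared) || max_shared >= min_shared,
            max_cloud_degree >= 1, anchor_dropout >= 1)
  structure(list(eps = as.integer(eps), maxk = maxk,
                 min_shared = min_shared, max_shared = max_shared,
                 max_cloud_degree = max_cloud_degree,
                 anchor_dropout = as.integer(anchor_dropout)),
            class = "deconv_params")
}

#' @export
print.deconv_params <- function(x, ...) {
  cat(sprintf(paste0("deconv_params: eps=%s maxk=%s min_shared=%s ",
                     "max_shared=%s max_cloud_degree=%s anchor_dropout=%s\n"),
              x$eps, x$maxk, x$min_shared,
              if (is.na(x$max_shared)) "auto" else x$max_shared,
              x$max_cloud_degree, x$anchor_dropout))
  invisible(x)
}

# Precomputed token index shared by all anchors of one run:
#   tok      — (token, read_id, barcode) restricted to retained tokens
#   cloud_tok— distinct (token, barcode)
#   specific — (token, barcode) pairs where the token occurs in exactly one
#              read of that cloud
deconv_index <- function(cs, vocab) {
  stopifnot(inherits(cs, "cloud_set"), inherits(vocab, "vocabulary"))
  if (is.null(vocab$retained))
    stop("vocabulary has not been filtered; call filter_vocabulary() first",
         call. = FALSE)
  tok <- cs$tokens[token %chin% vocab$retained]
  per_cloud <- tok[, .(n_reads = .N), by = .(token, barcode)]
  specific <- per_cloud[n_reads == 1L, .(token, barcode)]
  setkey(tok, token)
  setkey(specific, token)
  list(tok = tok, cloud_tok = unique(tok[, .(token, barcode)]),
       specific = specific)
}

anchor_max_shared <- function(n_anchor_tokens, params) {
  if (!is.na(params$max_shared)) return(params$max_shared)
  max(0.5 * n_anchor_tokens, params$min_shared)
}

#' Candidate foreign clouds for an anchor
#'
#' Returns the foreign clouds whose retained-token intersection with the
#' anchor cloud has size `s` with `min_shared <= s <= max_shared`. Pairs
#' sharing too few tokens are uninformative; pairs sharing too many likely
#' reflect low-complexity or conserved sequence, not a genuine single
#' fragment overlap.
#'
#' @param anchor_barcode barcode of the cloud being deconvolved.
#' @param cs a `cloud_set`.
#' @param vocab a filtered `vocabulary`.
#' @param params a [deconv_params()] object.
#' @param index optional precomputed index (internal use).
#' @return data.table with columns `barcode`, `shared` (intersection size),
#'   sorted by barcode.
#' @export
candidate_clouds <- function(anchor_barcode, cs, vocab,
                             params = deconv_params(), index = NULL) {
  if (is.null(index)) index <- deconv_index(cs, vocab)
  atok <- index$cloud_tok[barcode == anchor_barcode, token]
  if (length(atok) == 0L)
    return(data.table(barcode = character(0), shared = integer(0)))
  hits <- index$cloud_tok[token %chin% atok & barcode != anchor_barcode,
                          .(shared = .N), by = barcode]
  ms <- anchor_max_shared(length(atok), params)
  out <- hits[shared >= params$min_shared & shared <= ms]
  setkey(out, barcode)
  out[]
}

#' Bipartite read / foreign-cloud graph for an anchor
#'
#' An edge joins anchor read `r` to foreign cloud `B` iff some retained token
#' of `r` occurs in **exactly one** read of `B` (a fast proxy for a genuine
#' read-level overlap). Foreign-cloud nodes touching more than
#' `max_cloud_degree` anchor reads are then removed with their edges.
#'
#' @inheritParams candidate_clouds
#' @param candidates output of [candidate_clouds()] for this anchor.
#' @return data.table of edges with columns `read_id`, `barcode`.
#' @export
build_bipartite <- function(anchor_barcode, candidates, cs, vocab,
                            params = deconv_params(), index = NULL) {
  if (is.null(index)) index <- deconv_index(cs, vocab)
  empty <- data.table(read_id = character(0), barcode = character(0))
  if (nrow(candidates) == 0L) return(empty)
  art <- index$tok[barcode == anchor_barcode, .(read_id, token)]
  if (nrow(art) == 0L) return(empty)
  spec <- index$specific[barcode %chin% candidates$barcode]
  edges <- unique(merge(art, spec, by = "token",
                        allow.cartesian = TRUE)[, .(read_id, barcode)])
  if (is.finite(params$max_cloud_degree) && nrow(edges) > 0L) {
    deg <- edges[, .(degree = .N), by = barcode]
    edges <- edges[barcode %chin% deg[degree <= params$max_cloud_degree, barcode]]
  }
  setkey(edges, read_id, barcode)
  edges[]
}

#' Remove unspecific reads from a bipartite graph
#'
#' Reads matched to more than `maxk` foreign clouds are removed with their
#' incident edges: such reads are dominated by repetitive or conserved
#' sequence and would glue unrelated fragments together.
#'
#' @param edges bipartite edge table (`read_id`, `barcode`).
#' @param maxk maximum read degree.
#' @return Filtered edge table.
#' @export
prune_reads <- function(edges, maxk) {
  if (nrow(edges) == 0L) return(edges)
  deg <- edges[, .(degree = .N), by = read_id]
  edges[read_id %chin% deg[degree <= maxk, read_id]]
}

#' Project a bipartite graph to read-read co-occurrence weights
#'
#' The similarity of two anchor reads is the number of foreign clouds
#' adjacent to both of them in the (pruned) bipartite graph.
#'
#' @param edges bipartite edge table (`read_id`, `barcode`).
#' @return data.table with columns `r1`, `r2` (`r1 < r2`), `weight`.
#' @export
read_adjacency <- function(edges) {
  empty <- data.table(r1 = character(0), r2 = character(0),
                      weight = integer(0))
  if (nrow(edges) == 0L) return(empty)
  pairs <- merge(edges, edges, by = "barcode", allow.cartesian = TRUE,
                 suffixes = c(".1", ".2"))[read_id.1 < read_id.2]
  if (nrow(pairs) == 0L) return(empty)
  w <- pairs[, .(weight = .N), by = .(r1 = read_id.1, r2 = read_id.2)]
  setkey(w, r1, r2)
  w[]
}

#' Cluster reads by thresholded connected components
#'
#' Keeps read-read edges with `weight >= eps`, finds connected components of
#' the resulting graph, and discards components of a single read. This is a
#' graph analogue of DBSCAN: `eps` is the density threshold, components are
#' the clusters. Clusters are numbered 1..m in order of their smallest member
#' read id, so output is invariant to input permutation.
#'
#' @param weights read-read weight table from [read_adjacency()].
#' @param eps minimum weight for an edge to survive.
#' @return List of character vectors (sorted read ids), one per cluster of
#'   size >= 2.
#' @export
cluster_reads <- function(weights, eps) {
  strong <- weights[weight >= eps]
  if (nrow(strong) == 0L) return(list())
  g <- igraph::graph_from_data_frame(strong[, .(r1, r2)], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  members <- members[lengths(members) >= 2L]
  members[order(vapply(members, `[`, character(1), 1L))] |>
    unname()
}

#' Deconvolve one anchor read cloud
#'
#' Runs the full per-anchor chain — candidate selection, bipartite graph
#' construction, unspecific-read pruning, read-read projection, component
#' clustering — and reports a cluster index for every read of the anchor.
#' Reads in no cluster get index 0 (unassigned).
#'
#' @inheritParams candidate_clouds
#' @return data.table with columns `read_id`, `barcode`, `cluster`
#'   (0 = unassigned), one row per anchor read.
#' @export
deconvolve_cloud <- function(anchor_barcode, cs, vocab,
                             params = deconv_params(), index = NULL) {
  if (is.null(index)) index <- deconv_index(cs, vocab)
  cand <- candidate_clouds(anchor_barcode, cs, vocab, params, index)
  edges <- build_bipartite(anchor_barcode, cand, cs, vocab, params, index)
  edges <- prune_reads(edges, params$maxk)
  clusters <- cluster_reads(read_adjacency(edges), params$eps)
  out <- cs$reads[barcode == anchor_barcode, .(read_id, barcode)]
  out[, cluster := 0L]
  for (i in seq_along(clusters))
    out[read_id %chin% clusters[[i]], cluster := i]
  setkey(out, read_id)
  out[]
}

#' Deconvolve every eligible read cloud
#'
#' Applies [deconvolve_cloud()] to every cloud with at least `anchor_dropout`
#' reads. Smaller clouds are skipped as anchors but still serve as foreign
#' clouds. The comparison of every anchor against all other clouds makes the
#' algorithm O(n^2) in the number of read clouds.
#'
#' @param cs a `cloud_set` (after [drop_small_clouds()]).
#' @param vocab a filtered `vocabulary`.
#' @param params a [deconv_params()] object.
#' @param verbose report progress every 500 anchors.
#' @return A `deconvolution` object: list with `assignments` (data.table:
#'   `read_id`, `barcode`, `cluster`, `cloud_id = "<barcode>.<cluster>"`,
#'   covering the reads of all anchors) and `params`.
#' @export
deconvolve_all <- function(cs, vocab, params = deconv_params(),
                           verbose = FALSE) {
  index <- deconv_index(cs, vocab)
  sizes <- cloud_sizes(cs)
  anchors <- sort(sizes[n_reads >= params$anchor_dropout, barcode])
  # pre-split per-barcode views once instead of subsetting per anchor
  tok_by_bc <- split(index$tok[, .(read_id, token)], index$tok$barcode)
  res <- vector("list", length(anchors))
  for (j in seq_along(anchors)) {
    a <- anchors[[j]]
    art <- tok_by_bc[[a]]
    out <- cs$reads[barcode == a, .(read_id, barcode)]
    out[, cluster := 0L]
    if (!is.null(art) && nrow(art) > 0L) {
      atok <- unique(art$token)
      hits <- index$cloud_tok[token %chin% atok & barcode != a,
                              .(shared = .N), by = barcode]
      ms <- anchor_max_shared(length(atok), params)
      cand <- hits[shared >= params$min_shared & shared <= ms, barcode]
      if (length(cand) > 0L) {
        spec <- index$specific[barcode %chin% cand]
        edges <- unique(merge(art, spec, by = "token",
                              allow.cartesian = TRUE)[, .(read_id, barcode)])
        if (is.finite(params$max_cloud_degree) && nrow(edges) > 0L) {
          cdeg <- edges[, .N, by = barcode]
          edges <- edges[barcode %chin% cdeg[N <= params$max_cloud_degree,
                                             barcode]]
        }
        edges <- prune_reads(edges, params$maxk)
        clusters <- cluster_reads(read_adjacency(edges), params$eps)
        for (i in seq_along(clusters))
          out[read_id %chin% clusters[[i]], cluster := i]
      }
    }
    res[[j]] <- out
    if (verbose && j %% 500L == 0L)
      message(sprintf("deconvolved %d / %d anchors", j, length(anchors)))
  }
  assignments <- if (length(res)) rbindlist(res)
                 else data.table(read_id = character(0),
                                 barcode = character(0), cluster = integer(0))
  assignments[, cloud_id := paste(barcode, cluster, sep = ".")]
  setkey(assignments, barcode, read_id)
  structure(list(assignments = assignments[], params = params),
            class = "deconvolution")
}

#' @export
print.deconvolution <- function(x, ...) {
  a <- x$assignments
  cat(sprintf(
    "deconvolution: %d anchors, %d reads, %d enhanced clouds, %d reads unassigned\n",
    uniqueN(a$barcode), nrow(a),
    uniqueN(a[cluster > 0L, cloud_id]), a[cluster == 0L, .N]))
  invisible(x)
}

#' Write deconvolution assignments as TSV
#'
#' One row per read: `read_id`, `barcode`, `cluster` (0 = unassigned).
#'
#' @param deconv a `deconvolution` object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(deconv, path) {
  fwrite(deconv$assignments[, .(read_id, barcode, cluster)], path, sep = "\t")
  invisible(path)
}
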