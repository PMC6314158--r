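library(data.table)

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Brute-force minimizer oracle: enumerates every window explicitly and takes
# the canonical k-mer with the smallest hash (leftmost on ties). Windows are
# formed over N-free k-mers only; fewer than w valid k-mers = one window.
oracle_minimizer_set <- function(seq, params) {
  k <- params$k; w <- params$w
  n <- nchar(seq)
  if (n < k + w - 1) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  kmers <- canonical_kmer(kmers[valid])
  m <- length(kmers)
  if (m == 0L) return(character(0))
  h <- hash_kmer(kmers, params$seed)
  ww <- min(w, m)
  picked <- character(0)
  for (i in seq_len(m - ww + 1L)) {
    win <- i:(i + ww - 1L)
    best <- win[which(h[win] == min(h[win]))[1L]]  # leftmost min
    picked <- c(picked, kmers[best])
  }
  sort(unique(picked))
}

# Union-find connected components, independent of igraph.
oracle_components <- function(edges_r1, edges_r2) {
  nodes <- sort(unique(c(edges_r1, edges_r2)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_r1)) {
    ra <- find(edges_r1[i]); rb <- find(edges_r2[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  comps <- comps[lengths(comps) >= 2L]
  unname(comps[order(vapply(comps, `[`, character(1), 1L))])
}

# Construct a cloud_set directly from a token table, bypassing sequences, to
# unit-test the graph logic in isolation.
fake_cloud_set <- function(tokens) {
  tokens <- as.data.table(tokens)
  reads <- unique(tokens[, .(read_id, barcode)])
  reads[, `:=`(seq1 = NA_character_, seq2 = NA_character_)]
  setkey(reads, barcode, read_id)
  setkey(tokens, token)
  structure(list(reads = reads, tokens = tokens,
                 params = hash_params(), n_unbarcoded = 0L),
            class = "cloud_set")
}

fake_vocabulary <- function(tokens, retained = NULL) {
  tokens <- as.data.table(tokens)
  counts <- tokens[, .(count = .N), by = token]
  structure(list(counts = counts, mean_count = mean(counts$count),
                 retained = if (is.null(retained)) counts$token else retained),
            class = "vocabulary")
}

# Small taxonomy: root -> 2 genera -> 2 species each.
toy_taxonomy <- function() {
  read_taxonomy(data.frame(
    taxon_id  = c("1", "g1", "g2", "s11", "s12", "s21", "s22"),
    parent_id = c("1",  "1",  "1", "g1",  "g1",  "g2",  "g2"),
    rank = c("root", "genus", "genus", "species", "species", "species",
             "species"),
    name = c("root", "G1", "G2", "S11", "S12", "S21", "S22")))
}

# A small simulated dataset shared by several test files (built once).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      comm <- make_community(n_genomes = 3, genome_length = 50000, seed = 101)
      cache <<- list(
        community = comm,
        sim = simulate_linked_reads(
          comm, n_barcodes = 120, nf_mean = 2.5, fragment_length = 3000,
          C_r = 0.6, read_length = 100, insert_size = 300,
          error_rate = 0, seed = 102))
    }
    cache
  }
})
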