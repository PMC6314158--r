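Package: linkclouds
Title: Barcode Deconvolution for Linked-Read Metagenomic Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions linked-read (read cloud) barcoded short reads into
    groups of reads derived from single long DNA fragments ("enhanced read
    clouds"). Reads sharing a 3' barcode are sketched with minimizer
    (winnowing) k-mer hashing, matched against foreign read clouds through a
    bipartite read/cloud graph, and clustered by connected components of the
    projected read-read graph. Includes the closed-form generative model of
    fragment overlap between read clouds with a Monte-Carlo verifier, an
    information-theoretic recoverability bound, a synthetic linked-read
    metagenome simulator with ground truth, purity and Shannon-index
    evaluation against truth, a bag-of-minimizers document exporter, and
    taxonomic promotion of unspecific per-read classifications within read
    clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
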