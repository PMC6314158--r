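# linkclouds

Barcode deconvolution for linked-read (read cloud) metagenomic sequencing.

Linked-read technologies (10x Chromium and kin) tag short reads with a 3'
barcode shared by all reads from one microfluidic partition. Each partition
holds roughly 2–20 long DNA fragments, so a *read cloud* — the reads sharing
a barcode — mixes several fragments, usually from several genomes. For
metagenomes, where reference genomes are incomplete or absent, `linkclouds`
partitions each read cloud into **enhanced read clouds**, groups of reads
intended to derive from a single long fragment, using only k-mer overlap
between clouds:

1. reads are sketched with minimizers — per window of *w* consecutive
   k-mers, the canonical k-mer with the smallest seeded hash; reads with an
   exact overlap ≥ *w* + *k* − 1 bases are guaranteed to share one;
2. singleton and stop-word tokens (count > 10× the mean) are discarded;
3. for each *anchor* cloud, a bipartite graph joins anchor reads to foreign
   clouds containing a token specific to exactly one of their reads;
   unspecific reads (degree > *maxk*) are pruned;
4. the graph is projected to read–read weights (number of shared foreign
   clouds) and thresholded at *eps*; connected components of size ≥ 2 are
   the enhanced read clouds.

The package also implements the closed-form generative model behind the
method — fragment collision probability *p_f* = 1/(2 *N_g*), the
distribution {X(0), X(1), X(≥2)} of fragments shared by two clouds, the
*C_r*² repeat-overlap expectation, and the community-recovery bound
*N_r*/ln *N_r* · (*p* − *q*)² > *N_f* — plus a Monte-Carlo verifier, a
synthetic linked-read simulator with ground truth, purity/Shannon-index
evaluation, a bag-of-minimizers document exporter for topic-model
clustering, and taxonomic promotion of unspecific per-read classifications
within (enhanced) read clouds.

## Worked example

Simulate a small skewed community, deconvolve it, and score the result
against the simulator's truth table:

```r
library(linkclouds)

community <- make_community(n_genomes = 3, genome_length = 50000, seed = 1)
sim <- simulate_linked_reads(community, n_barcodes = 150, nf_mean = 2.5,
                             fragment_length = 3000, C_r = 0.6, seed = 2)

clouds <- cloud_set_from_reads(sim$reads, hash_params())   # k=30, w=40
clouds <- drop_small_clouds(clouds, 2)
vocab  <- filter_vocabulary(build_vocabulary(clouds))
dec    <- deconvolve_all(clouds, vocab,
                         deconv_params(eps = 2, maxk = 50, anchor_dropout = 5))
dec
#> deconvolution: 149 anchors, 3520 reads, 320 enhanced clouds, 562 reads unassigned

scores <- summarize_deconvolution(dec, clouds, sim$truth)
scores$summary
#>       group n_clouds mean_purity median_purity mean_shannon median_shannon
#> 1: enhanced      320   0.9213148     1.0000000    0.1429504      0.0000000
#> 2: standard      149   0.5856139     0.5217391    0.7867023      0.6931472
#>    frac_perfect mean_size
#> 1:    0.8218750   9.24375
#> 2:    0.2214765  23.62416
```

The 149 raw barcodes (mean purity 0.59: each mixes ~2.5 fragments) are split
into 320 enhanced read clouds with mean purity 0.92; 82% of them are perfect
(*P* = 1, *H* = 0), i.e. contain reads of exactly one fragment. Purity is the
dominant fragment's share of a cloud; the Shannon index is the entropy of
the cloud's fragment composition (0 for a pure cloud, ln 2 ≈ 0.69 for a
50/50 mix — the standard barcodes' median).

The model functions give the closed-form rationale: at *N_f* = 5 fragments
per cloud and *N_g* = 100 fragments per genome,

```r
overlap_distribution(5, fragment_collision_prob(100))
#>          X0          X1      X2plus
#> 0.882220243 0.113070684 0.004709073
```

so two clouds are ~24× more likely to share exactly one fragment than
several — cloud co-occurrence is a nearly unambiguous positional signal.

A command-line wrapper with `simulate`, `deconvolve`, `model`, `evaluate`,
`export-docs` and `promote` subcommands is installed at
`system.file("scripts", "linkclouds", package = "linkclouds")`.

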