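# Crafted token tables exercise the graph logic without real sequences.

test_that("candidate clouds are exactly those within the shared-token bounds", {
  # anchor A shares 1, 3 and 50 tokens with B1, B2, B3
  tok <- rbindlist(list(
    data.table(read_id = "a1", barcode = "A",
               token = paste0("t", 1:60)),
    data.table(read_id = "b1", barcode = "B1", token = "t1"),
    data.table(read_id = "b2", barcode = "B2", token = paste0("t", 1:3)),
    data.table(read_id = "b3", barcode = "B3", token = paste0("t", 1:50))))
  cs <- fake_cloud_set(tok)
  v <- fake_vocabulary(tok)
  cand <- candidate_clouds("A", cs, v,
                           deconv_params(min_shared = 2, max_shared = 10))
  expect_equal(cand$barcode, "B2")
  expect_equal(cand$shared, 3L)

  # no shared tokens anywhere -> empty
  tok2 <- data.table(read_id = c("a1", "b1"), barcode = c("A", "B1"),
                     token = c("x", "y"))
  cand2 <- candidate_clouds("A", fake_cloud_set(tok2), fake_vocabulary(tok2),
                            deconv_params(min_shared = 1))
  expect_equal(nrow(cand2), 0L)
})

test_that("candidate set equals an all-pairs intersection oracle", {
  set.seed(40)
  universe <- paste0("tok", 1:40)
  tok <- rbindlist(lapply(paste0("B", 1:12), function(bc) {
    data.table(read_id = paste0(bc, "_r1"), barcode = bc,
               token = sample(universe, sample(3:20, 1)))
  }))
  cs <- fake_cloud_set(tok)
  v <- fake_vocabulary(tok)
  p <- deconv_params(min_shared = 2, max_shared = 8)
  for (anchor in c("B1", "B5", "B9")) {
    got <- candidate_clouds(anchor, cs, v, p)
    atoks <- unique(tok[barcode == anchor, token])
    oracle <- sapply(setdiff(paste0("B", 1:12), anchor), function(b)
      length(intersect(atoks, unique(tok[barcode == b, token]))))
    oracle <- sort(names(oracle[oracle >= 2 & oracle <= 8]))
    expect_equal(got$barcode, oracle)
  }
})

test_that("bipartite edges require a token specific to one foreign read", {
  # t1 occurs in TWO reads of B1 (no edge); t2 in exactly one read of B2
  tok <- rbindlist(list(
    data.table(read_id = "a1", barcode = "A", token = c("t1", "t2")),
    data.table(read_id = c("b1", "b2"), barcode = "B1", token = "t1"),
    data.table(read_id = "b3", barcode = "B2", token = "t2")))
  cs <- fake_cloud_set(tok)
  v <- fake_vocabulary(tok)
  p <- deconv_params(min_shared = 1)
  cand <- candidate_clouds("A", cs, v, p)
  edges <- build_bipartite("A", cand, cs, v, p)
  expect_equal(edges, data.table(read_id = "a1", barcode = "B2",
                                 key = c("read_id", "barcode")))
})

test_that("a read uniquely matched in three clouds has degree three", {
  tok <- rbindlist(list(
    data.table(read_id = "a1", barcode = "A", token = c("t1", "t2", "t3")),
    data.table(read_id = "b1", barcode = "B1", token = "t1"),
    data.table(read_id = "b2", barcode = "B2", token = "t2"),
    data.table(read_id = "b3", barcode = "B3", token = "t3")))
  cs <- fake_cloud_set(tok)
  v <- fake_vocabulary(tok)
  p <- deconv_params(min_shared = 1)
  edges <- build_bipartite("A", candidate_clouds("A", cs, v, p), cs, v, p)
  expect_equal(nrow(edges), 3L)
  expect_equal(unique(edges$read_id), "a1")
})

test_that("bipartite edge set equals a triple-loop oracle on random instances", {
  set.seed(41)
  for (rep in 1:10) {
    universe <- paste0("t", 1:25)
    tok <- rbindlist(lapply(c("A", paste0("B", 1:6)), function(bc) {
      rbindlist(lapply(1:4, function(i)
        data.table(read_id = paste0(bc, "_r", i), barcode = bc,
                   token = sample(universe, sample(2:6, 1)))))
    }))
    tok <- unique(tok)
    cs <- fake_cloud_set(tok)
    v <- fake_vocabulary(tok)
    p <- deconv_params(min_shared = 1, max_shared = 1e6)
    cand <- candidate_clouds("A", cs, v, p)
    edges <- build_bipartite("A", cand, cs, v, p)
    # oracle: loop over (read, cloud, token)
    oracle <- list()
    for (r in unique(tok[barcode == "A", read_id])) {
      rt <- tok[read_id == r, token]
      for (b in cand$barcode) {
        hit <- FALSE
        for (t in rt) {
          if (nrow(tok[barcode == b & token == t]) == 1L) hit <- TRUE
        }
        if (hit) oracle[[length(oracle) + 1L]] <-
            data.table(read_id = r, barcode = b)
      }
    }
    oracle <- if (length(oracle)) setkey(rbindlist(oracle), read_id, barcode)
              else data.table(read_id = character(0), barcode = character(0))
    expect_equal(as.data.frame(edges), as.data.frame(oracle))
  }
})

test_that("prune_reads removes exactly the reads above maxk", {
  edges <- data.table(
    read_id = rep(c("r1", "r2"), c(5L, 2L)),
    barcode = paste0("B", c(1:5, 1:2)))
  expect_equal(nrow(prune_reads(copy(edges), Inf)), 7L)
  pruned <- prune_reads(copy(edges), 4L)
  expect_equal(unique(pruned$read_id), "r2")
  set.seed(42)
  for (rep in 1:10) {
    e <- unique(data.table(read_id = paste0("r", sample(1:8, 30, TRUE)),
                           barcode = paste0("B", sample(1:10, 30, TRUE))))
    maxk <- sample(1:5, 1)
    deg <- table(e$read_id)
    keep <- names(deg[deg <= maxk])
    expect_setequal(unique(prune_reads(e, maxk)$read_id),
                    intersect(unique(e$read_id), keep))
  }
})

test_that("read adjacency counts common foreign clouds", {
  e <- data.table(read_id = c("r1", "r1", "r2", "r2"),
                  barcode = c("B1", "B2", "B3", "B4"))
  expect_equal(nrow(read_adjacency(e)), 0L)   # disjoint cloud sets
  e2 <- data.table(read_id = rep(c("r1", "r2"), each = 3),
                   barcode = rep(c("B1", "B2", "B3"), 2))
  w <- read_adjacency(e2)
  expect_equal(w$weight, 3L)
  set.seed(43)
  for (rep in 1:10) {
    e <- unique(data.table(read_id = paste0("r", sample(1:6, 25, TRUE)),
                           barcode = paste0("B", sample(1:8, 25, TRUE))))
    w <- read_adjacency(e)
    rs <- sort(unique(e$read_id))
    for (i in seq_along(rs)) for (j in seq_len(i - 1L)) {
      common <- length(intersect(e[read_id == rs[i], barcode],
                                 e[read_id == rs[j], barcode]))
      got <- w[r1 == rs[j] & r2 == rs[i], weight]
      expect_equal(if (length(got)) got else 0L, common)
    }
  }
})

test_that("clustering is thresholded connected components, size >= 2", {
  w <- data.table(r1 = c("r1", "r2"), r2 = c("r2", "r3"), weight = c(2L, 2L))
  expect_equal(cluster_reads(w, 2), list(c("r1", "r2", "r3")))
  expect_equal(cluster_reads(w, 3), list())
})

test_that("cluster_reads equals a union-find oracle across eps values", {
  set.seed(44)
  for (rep in 1:60) {
    n <- sample(4:14, 1)
    m <- sample(3:20, 1)
    w <- unique(data.table(
      r1 = paste0("r", sample(n, m, TRUE)),
      r2 = paste0("r", sample(n, m, TRUE)),
      weight = sample(1:4, m, TRUE)))[r1 < r2]
    prev <- NULL
    for (eps in 1:4) {
      got <- cluster_reads(w, eps)
      strong <- w[weight >= eps]
      expect_equal(got, oracle_components(strong$r1, strong$r2))
      # refinement: each cluster at eps is inside one cluster at eps-1
      if (!is.null(prev) && length(got)) {
        for (cl in got) {
          container <- Filter(function(pc) all(cl %in% pc), prev)
          expect_length(container, 1L)
        }
      }
      prev <- got
    }
  }
})

test_that("deconvolve_cloud equals the five operations chained", {
  ss <- small_sim()
  cs <- drop_small_clouds(cloud_set_from_reads(ss$sim$reads, hash_params()), 2)
  v <- filter_vocabulary(build_vocabulary(cs))
  p <- deconv_params(eps = 2, maxk = 50, anchor_dropout = 5)
  idx <- linkclouds:::deconv_index(cs, v)
  anchors <- cloud_sizes(cs)[n_reads >= 8, barcode][1:3]
  for (a in anchors) {
    direct <- deconvolve_cloud(a, cs, v, p, idx)
    cand <- candidate_clouds(a, cs, v, p, idx)
    edges <- prune_reads(build_bipartite(a, cand, cs, v, p, idx), p$maxk)
    clusters <- cluster_reads(read_adjacency(edges), p$eps)
    manual <- cs$reads[barcode == a, .(read_id, barcode)][, cluster := 0L]
    for (i in seq_along(clusters))
      manual[read_id %chin% clusters[[i]], cluster := i]
    setkey(manual, read_id)
    expect_equal(as.data.frame(direct), as.data.frame(manual))
  }
})

test_that("deconvolve_all equals per-anchor deconvolve_cloud and is deterministic", {
  ss <- small_sim()
  cs <- drop_small_clouds(cloud_set_from_reads(ss$sim$reads, hash_params()), 2)
  v <- filter_vocabulary(build_vocabulary(cs))
  p <- deconv_params(eps = 2, maxk = 50, anchor_dropout = 5)
  dec1 <- deconvolve_all(cs, v, p)
  dec2 <- deconvolve_all(cs, v, p)
  expect_identical(dec1$assignments, dec2$assignments)
  idx <- linkclouds:::deconv_index(cs, v)
  anchors <- sort(cloud_sizes(cs)[n_reads >= p$anchor_dropout, barcode])
  expect_setequal(unique(dec1$assignments$barcode), anchors)
  for (a in anchors[c(1, 5, 9)]) {
    expect_equal(
      as.data.frame(dec1$assignments[barcode == a,
                                     .(read_id, barcode, cluster)]),
      as.data.frame(deconvolve_cloud(a, cs, v, p, idx)))
  }
})

test_that("output clusters partition a subset of anchor reads, min size 2", {
  ss <- small_sim()
  cs <- drop_small_clouds(cloud_set_from_reads(ss$sim$reads, hash_params()), 2)
  v <- filter_vocabulary(build_vocabulary(cs))
  dec <- deconvolve_all(cs, v, deconv_params(eps = 2, maxk = 50,
                                             anchor_dropout = 5))
  a <- dec$assignments
  expect_equal(anyDuplicated(a$read_id), 0L)  # one cluster per read
  csize <- a[cluster > 0L, .N, by = cloud_id]
  expect_true(all(csize$N >= 2L))
  # every assigned read belongs to its anchor cloud
  merged <- cs$reads[a, on = c("read_id", "barcode"), nomatch = NULL]
  expect_equal(nrow(merged), nrow(a))
})

test_that("a single isolated cloud yields no clusters", {
  set.seed(45)
  reads <- data.frame(read_id = paste0("r", 1:5), barcode = "only",
                      seq1 = replicate(5, random_dna(120)))
  cs <- cloud_set_from_reads(reads, hash_params(k = 15, w = 10))
  v <- filter_vocabulary(build_vocabulary(cs))
  dec <- deconvolve_all(cs, v, deconv_params(anchor_dropout = 2))
  expect_true(all(dec$assignments$cluster == 0L))
})

test_that("raising eps never merges previously separate clusters", {
  ss <- small_sim()
  cs <- drop_small_clouds(cloud_set_from_reads(ss$sim$reads, hash_params()), 2)
  v <- filter_vocabulary(build_vocabulary(cs))
  base <- deconv_params(eps = 2, maxk = 50, anchor_dropout = 5)
  hi <- deconv_params(eps = 4, maxk = 50, anchor_dropout = 5)
  d2 <- deconvolve_all(cs, v, base)$assignments
  d4 <- deconvolve_all(cs, v, hi)$assignments
  both <- merge(d2, d4, by = c("read_id", "barcode"),
                suffixes = c(".lo", ".hi"))
  # reads sharing a cluster at eps=4 must share one at eps=2
  hi_cl <- split(both[cluster.hi > 0L],
                 by = c("barcode", "cluster.hi"))
  for (grp in hi_cl) {
    expect_equal(uniqueN(grp$cluster.lo), 1L)
    expect_true(all(grp$cluster.lo > 0L))
  }
})
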