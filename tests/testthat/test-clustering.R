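test_that("a single satellite family forms one dominant cluster", {
  tpl <- fixture_templates()
  # arrays longer than the insert so fragment provenance is unambiguous
  g <- build_genome(genome_spec(
    "SATC", 300000,
    list(list(template = tpl$helosat, copies = 100, divergence = 0.01,
              monomers_per_copy = 30)),
    seed = 13))
  r <- simulate_reads(g, coverage = 0.05, insert_size = 300, seed = 14,
                      species_tag = "SATC")
  cs <- build_cluster_graph(r)
  expect_gte(nrow(cs$clusters), 1)
  # satellite reads identified independently of the clustering aligner:
  # at least three monomer copies present in the read sequence
  monomer <- tpl$helosat$segments[[1]]$seq
  dna <- Biostrings::DNAStringSet(r$seq)
  n_mono <- Biostrings::vcountPattern(monomer, dna, max.mismatch = 3) +
    Biostrings::vcountPattern(revcomp_chr(monomer), dna, max.mismatch = 3)
  sat_reads <- names(r$seq)[n_mono >= 3]
  expect_gte(length(sat_reads), 20)
  expect_gte(sum(cs$membership[sat_reads] == "CL1", na.rm = TRUE) /
               length(sat_reads), 0.95)
})

test_that("families far below the identity threshold never merge", {
  tpl <- fixture_templates()
  g <- build_genome(genome_spec(
    "TWOF", 200000,
    list(list(template = tpl$cacta, copies = 80, divergence = 0.01),
         list(template = tpl$line, copies = 80, divergence = 0.01)),
    seed = 15))
  r <- simulate_reads(g, coverage = 0.08, insert_size = 300, seed = 16,
                      species_tag = "TWOF")
  cs <- build_cluster_graph(r)
  prov <- r$provenance[sub("/[12]$", "", names(r$seq))]
  names(prov) <- names(r$seq)
  for (id in cs$clusters$id) {
    members <- cluster_members(cs, id)
    fams <- unique(prov[members])
    fams <- setdiff(fams, c("single-copy", "ambiguous"))
    expect_lte(length(fams), 1)
  }
})

test_that("clustering is invariant to read input order", {
  reads <- fixture_clean_reads()$a
  cs1 <- build_cluster_graph(reads)
  perm <- withr::with_seed(99, sample(seq_along(reads$seq)))
  shuffled <- read_set(reads$seq[perm], reads$qual[perm],
                       reads$species_tag, reads$read_length)
  cs2 <- build_cluster_graph(shuffled)
  expect_identical(cs1$membership, cs2$membership)
  expect_identical(cs1$clusters, cs2$clusters)
})

test_that("cluster sizes and the low/single-copy pool conserve reads", {
  fx <- fixture_comparative()
  cs <- fx$cs
  expect_equal(sum(cs$clusters$size) + sum(is.na(cs$membership)),
               length(cs$membership))
  for (sp in cs$species) {
    in_clusters <- sum(cs$clusters[[paste0("reads_", sp)]])
    in_pool <- sum(is.na(cs$membership) &
                     substr(names(cs$membership), 1, 4) == sp)
    expect_equal(in_clusters + in_pool, cs$analyzed[[sp]])
  }
  # per-species counts sum to cluster size
  expect_equal(rowSums(as.matrix(cs$clusters[, paste0("reads_", cs$species)])),
               as.numeric(cs$clusters$size))
})

test_that("prefiltered clustering matches brute-force all-pairs clustering", {
  reads <- fixture_clean_reads()$a   # 150 reads
  fast <- build_cluster_graph(reads, use_prefilter = TRUE)
  brute <- build_cluster_graph(reads, use_prefilter = FALSE)
  expect_identical(fast$membership, brute$membership)
})

test_that("superclusters join structure-split clusters through mate pairs", {
  # two divergent segments, reads manually paired across them
  segX <- random_dna(200, seed = 61)
  segY <- random_dna(200, seed = 62)
  n <- 8
  seqs <- character(0)
  for (i in seq_len(n)) {
    seqs <- c(seqs, substr(segX, i, i + 99), substr(segY, i, i + 99))
  }
  rs <- manual_read_set(seqs, tag = "SPLT")  # mate1 from X, mate2 from Y
  cs <- build_cluster_graph(rs)
  expect_equal(nrow(cs$clusters), 2)
  sc <- link_superclusters(cs, min_pairs = 5)
  expect_equal(length(unique(sc$supercluster)), 1)
  # unreachable threshold: superclusters collapse to clusters
  sc_inf <- link_superclusters(cs, min_pairs = Inf)
  expect_equal(length(unique(sc_inf$supercluster)), 2)
})

test_that("clusters without spanning pairs stay separate superclusters", {
  fx <- fixture_comparative()
  sc <- link_superclusters(fx$cs, min_pairs = 10000)
  expect_equal(length(unique(sc$supercluster)), nrow(fx$cs$clusters))
})

test_that("comparative clustering rejects duplicate species prefixes", {
  clean <- fixture_clean_reads()
  expect_error(comparative_cluster(list(clean$a, clean$a)), "duplicate")
})

test_that("species-specific clusters are flagged by zero counts", {
  fx <- fixture_comparative()
  cs <- fx$cs
  sat_id <- fx$ann$id[fx$ann$label == "satellite"][1]
  expect_false(is.na(sat_id))
  row <- cs$clusters[cs$clusters$id == sat_id, ]
  # the satellite is ~10x more abundant in TOYB
  expect_gt(row$reads_TOYB, 3 * max(1, row$reads_TOYA))
})
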