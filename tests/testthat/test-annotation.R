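test_that("clusters of simulated family reads receive their true lineage", {
  fx <- fixture_comparative()
  cs <- fx$cs
  ann <- fx$ann
  # match each sizeable cluster to its dominant read provenance
  prov <- c(fixture_clean_reads()$a$provenance,
            fixture_clean_reads()$b$provenance)
  truth <- fixture_genomes()$TOYA$truth
  fam2lin <- stats::setNames(truth$lineage, truth$family)
  big <- cs$clusters$id[cs$clusters$size >= 5]
  checked <- 0
  correct <- 0
  for (id in big) {
    fams <- prov[sub("/[12]$", "", cluster_members(cs, id))]
    fams <- fams[!(fams %in% c("single-copy", "ambiguous", "organelle"))]
    if (!length(fams)) next
    dominant <- names(sort(table(fams), decreasing = TRUE))[1]
    checked <- checked + 1
    if (ann$label[ann$id == id] == fam2lin[[dominant]]) correct <- correct + 1
  }
  expect_gte(checked, 3)
  expect_gte(correct / checked, 0.90)
})

test_that("clusters with no reference hits are unclassified", {
  # three mutually identical random reads cluster but match nothing
  seqs <- rep(random_dna(100, seed = 71), 4)
  rs <- manual_read_set(seqs, tag = "RAND")
  cs <- build_cluster_graph(rs)
  expect_equal(nrow(cs$clusters), 1)
  res <- classify_cluster(cs, "CL1", fixture_reference())
  expect_equal(res$label, "unclassified")
  expect_equal(res$support, 0)
  expect_error(classify_cluster(cs, "CL1", fixture_reference()[0, ]),
               "empty")
})

test_that("exact support ties break toward the smaller lineage label", {
  shared <- random_dna(300, seed = 72)
  ref <- data.frame(name = c("x1", "x2"),
                    lineage = c("Ty3/gypsy-Retand", "Ty1/copia-Angela"),
                    sequence = c(shared, shared), stringsAsFactors = FALSE)
  class(ref) <- c("repeat_reference", "data.frame")
  seqs <- rep(substr(shared, 1, 100), 4)
  rs <- manual_read_set(seqs, tag = "TIEB")
  cs <- build_cluster_graph(rs)
  res <- classify_cluster(cs, "CL1", ref)
  expect_equal(res$label, "Ty1/copia-Angela")   # lexicographically smaller
  expect_equal(res$runner_up, "Ty3/gypsy-Retand")
  expect_equal(res$support, res$runner_support)
})

test_that("satellite monomer detection finds the smallest period", {
  monomer <- random_dna(26, seed = 73)
  expect_equal(detect_satellite(strrep(monomer, 20)), 26L)
  # a dimer of the same unit still reports the 26 b period
  dimer <- strrep(paste0(monomer, monomer), 10)
  expect_equal(detect_satellite(dimer), 26L)
  # mutated copies still detected at 80% shift identity
  arr <- strrep(monomer, 20)
  set.seed(74)
  arr_mut <- skimrep:::mutate_sequence(arr, 0.05)
  expect_equal(detect_satellite(arr_mut), 26L)
  # a long monomer is rejected when too few copies fit
  expect_true(is.na(detect_satellite(strrep(random_dna(45, seed = 75), 2))))
})

test_that("random sequences practically never trigger satellite calls", {
  set.seed(76)
  calls <- vapply(seq_len(1000), function(i) {
    detect_satellite(random_dna(1000))
  }, integer(1))
  expect_true(all(is.na(calls)))
})

test_that("reference FASTA round-trips with lineage labels", {
  ref <- fixture_reference()
  path <- tempfile(fileext = ".fasta")
  write_reference_fasta(ref, path)
  back <- read_reference_fasta(path)
  expect_equal(back$name, ref$name)
  expect_equal(back$lineage, ref$lineage)
  expect_equal(back$sequence, ref$sequence)
})

test_that("lineage recovery stays high at 5% template divergence", {
  tpl <- fixture_templates()
  g <- build_genome(genome_spec(
    "DIVG", 400000,
    list(list(template = tpl$angela, copies = 120, divergence = 0.05),
         list(template = tpl$cacta, copies = 120, divergence = 0.05),
         list(template = tpl$rdna, copies = 60, divergence = 0.05)),
    seed = 81))
  r <- simulate_reads(g, coverage = 0.06, insert_size = 300,
                      error_rate = 0, seed = 82, species_tag = "DIVG")
  cs <- build_cluster_graph(r)
  ann <- annotate_clusters(cs, fixture_reference())
  prov <- r$provenance[sub("/[12]$", "", names(r$seq))]
  names(prov) <- names(r$seq)
  truth <- g$truth
  fam2lin <- stats::setNames(truth$lineage, truth$family)
  ok <- 0
  tot <- 0
  for (i in seq_len(nrow(ann))) {
    fams <- prov[cluster_members(cs, ann$id[i])]
    fams <- fams[!(fams %in% c("single-copy", "ambiguous"))]
    if (!length(fams)) next
    dominant <- names(sort(table(fams), decreasing = TRUE))[1]
    tot <- tot + 1
    if (ann$label[i] == fam2lin[[dominant]]) ok <- ok + 1
  }
  expect_gte(tot, 3)
  expect_gte(ok / tot, 0.90)
})
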