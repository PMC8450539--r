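test_that("satellite-only genome has exact truth genome proportion", {
  tpl <- fixture_templates()
  spec <- genome_spec("SATG", 200000,
                      list(list(template = tpl$helosat, copies = 100,
                                divergence = 0, monomers_per_copy = 10)),
                      seed = 7)
  g <- build_genome(spec)
  expect_equal(g$truth$bases, 100 * 10 * 26)
  expect_equal(g$truth$gp, 26000 / 200000)
  expect_equal(nchar(g$sequence), 200000)
})

test_that("zero-copy spec yields pure background with zero proportions", {
  tpl <- fixture_templates()
  spec <- genome_spec("NONE", 50000,
                      list(list(template = tpl$angela, copies = 0)),
                      seed = 3)
  g <- build_genome(spec)
  expect_equal(g$truth$gp, 0)
  expect_equal(nrow(g$intervals), 0)
  expect_equal(nchar(g$sequence), 50000)
})

test_that("truth bases and background partition the genome exactly", {
  for (g in fixture_genomes()) {
    covered <- sum(g$intervals$end - g$intervals$start + 1)
    expect_equal(sum(g$truth$bases), covered)
    expect_true(all(g$truth$gp >= 0))
    expect_lte(sum(g$truth$gp), 1)
    # intervals non-overlapping
    o <- order(g$intervals$start)
    s <- g$intervals$start[o]
    e <- g$intervals$end[o]
    expect_true(all(s[-1] > e[-length(e)]))
  }
})

test_that("shared families at scaled copy number keep genome proportions", {
  g <- fixture_genomes()
  ta <- g$TOYA$truth
  tb <- g$TOYB$truth
  shared <- intersect(ta$family, tb$family)
  shared <- setdiff(shared, "HeloSAT")  # satellite differs by design
  for (f in shared) {
    gp_a <- ta$gp[ta$family == f]
    gp_b <- tb$gp[tb$family == f]
    expect_lt(abs(gp_a - gp_b) / gp_a, 0.12)
  }
})

test_that("capacity violations and invalid family specs are rejected", {
  tpl <- fixture_templates()
  expect_error(
    genome_spec("BIG", 10000,
                list(list(template = tpl$angela, copies = 100))),
    "capacity.*Angela")
  expect_error(
    genome_spec("S", 10000,
                list(list(template = tpl$cacta, copies = 1, solo_ltrs = 2))),
    "solo_ltr")
})

test_that("read-pair count follows the coverage formula exactly", {
  tpl <- fixture_templates()
  g <- build_genome(genome_spec("FORM", 1e6,
                                list(list(template = tpl$cacta, copies = 10)),
                                seed = 5))
  r <- simulate_reads(g, coverage = 0.015, read_length = 100,
                      insert_size = 300, seed = 2)
  expect_equal(n_pairs(r), 75)   # 0.015 * 1e6 / (2 * 100)
  expect_equal(length(r$seq), 150)
  expect_error(simulate_reads(g, coverage = 0), "coverage")
  expect_error(simulate_reads(g, coverage = 0.1, read_length = 100,
                              insert_size = 150), "insert_size")
})

test_that("error-free reads are exact genome substrings up to strand", {
  tpl <- fixture_templates()
  g <- build_genome(genome_spec("EXCT", 100000,
                                list(list(template = tpl$retand, copies = 20,
                                          divergence = 0)),
                                seed = 9))
  r <- simulate_reads(g, coverage = 0.05, insert_size = 300,
                      error_rate = 0, seed = 4)
  found <- vapply(r$seq, function(s) {
    grepl(s, g$sequence, fixed = TRUE) ||
      grepl(revcomp_chr(s), g$sequence, fixed = TRUE)
  }, logical(1))
  expect_true(all(found))
})

test_that("identical seeds give byte-identical FASTQ output", {
  g <- fixture_genomes()$TOYA
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, 0.01, insert_size = 300, seed = 42), f1)
  write_fastq(simulate_reads(g, 0.01, insert_size = 300, seed = 42), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  f3 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(g, 0.01, insert_size = 300, seed = 43), f3)
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f3))))
})

test_that("provenance fraction tracks genome proportion at deep coverage", {
  tpl <- fixture_templates()
  # long satellite arrays (780 b > insert) make fragment-majority provenance
  # a clean estimator of the 20% truth proportion
  g <- build_genome(genome_spec(
    "PROV", 500000,
    list(list(template = tpl$helosat, copies = 128, divergence = 0,
              monomers_per_copy = 30)),
    seed = 11))
  gp_true <- g$truth$gp
  expect_equal(gp_true, 128 * 780 / 500000)
  r <- simulate_reads(g, coverage = 0.15, insert_size = 300, seed = 12)
  stems <- unique(sub("/[12]$", "", names(r$seq)))
  frac <- mean(r$provenance[stems] == "HeloSAT")
  n <- length(stems)
  se <- sqrt(gp_true * (1 - gp_true) / n)
  expect_lt(abs(frac - gp_true), 4 * se + 0.01)
})

test_that("organelle spiking adds the requested pair count with provenance", {
  reads <- fixture_clean_reads()$a
  org <- make_organelle_reference()
  expect_identical(spike_organelle(reads, org, 0), reads)
  spiked <- spike_organelle(reads, org, 0.10, insert_size = 300, seed = 8)
  added <- n_pairs(spiked) - n_pairs(reads)
  expect_equal(added, round(0.10 * n_pairs(reads)))
  expect_equal(sum(spiked$provenance == "organelle"), added)
  expect_error(spike_organelle(reads, org, 1.0), "fraction")
})
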