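test_that("junction tags are the 30-mers flanking the LTR/internal boundary", {
  tpl <- toy_ltr_template()
  tags <- extract_tags(tpl)
  ltr <- skimrep:::ltr_segment(tpl)
  internal <- skimrep:::internal_segment(tpl)
  expect_equal(tags$ltr3_tag, substr(ltr, 91, 120))
  expect_equal(tags$utr5_tag, substr(internal, 1, 30))
  expect_equal(tags$combined_tag, paste0(tags$ltr3_tag, tags$utr5_tag))
  expect_equal(nchar(tags$combined_tag), 60)
  # boundary form of the input
  tags2 <- extract_tags(list(sequence = paste0(ltr, internal),
                             boundary = 120))
  expect_equal(tags2$combined_tag, tags$combined_tag)
})

test_that("segments shorter than the tag length are rejected", {
  short <- repeat_template("short", "Ty1/copia-Ale",
                           ltr = random_dna(29, seed = 1),
                           internal = random_dna(100, seed = 2))
  expect_error(extract_tags(short), "shorter than the 30 nt tag")
  expect_error(extract_tags(fixture_templates()$cacta), "LTR")
})

test_that("the combined tag marks full-length copies but never solo-LTRs", {
  tpl <- toy_ltr_template()
  tags <- extract_tags(tpl)
  g <- build_genome(genome_spec(
    "TAGG", 400000,
    list(list(template = tpl, copies = 30, solo_ltrs = 30, divergence = 0)),
    seed = 17))
  iv <- g$intervals
  for (i in seq_len(nrow(iv))) {
    copy <- substr(g$sequence, iv$start[i], iv$end[i])
    hit <- grepl(tags$combined_tag, copy, fixed = TRUE)
    expect_equal(hit, iv$kind[i] == "full")
  }
})

test_that("Rsf formula limits on constructed read sets", {
  tpl <- toy_ltr_template()
  tags <- extract_tags(tpl)
  junction_read <- paste0(substr(tags$combined_tag, 1, 60),
                          random_dna(40, seed = 95))
  ltr_only_read <- paste0(random_dna(35, seed = 96), tags$ltr3_tag,
                          random_dna(35, seed = 97))
  # every LTR-3' read also spans the junction: Lx = LU, Rsf = 0
  rs0 <- manual_read_set(rep(junction_read, 20), tag = "RSFA")
  r0 <- rsf_count(rs0, tags)
  expect_equal(r0$lx, 20)
  expect_equal(r0$lu, 20)
  expect_equal(r0$rsf, 0)
  # 100 LTR-3' hits of which 20 junction-spanning: Rsf = 4 exactly
  rs1 <- manual_read_set(c(rep(junction_read, 20), rep(ltr_only_read, 80)),
                         tag = "RSFB")
  r1 <- rsf_count(rs1, tags)
  expect_equal(r1$lx, 100)
  expect_equal(r1$lu, 20)
  expect_equal(r1$rsf, 4.0)
  expect_lte(r1$lu, r1$lx)
  # no junction reads at all: flagged undefined, no division by zero
  rs2 <- manual_read_set(rep(ltr_only_read, 10), tag = "RSFC")
  r2 <- rsf_count(rs2, tags)
  expect_true(r2$undefined)
  expect_true(is.na(r2$rsf))
})

test_that("tag matching tolerates up to two substitutions and both strands", {
  tpl <- toy_ltr_template()
  tags <- extract_tags(tpl)
  mut <- tags$ltr3_tag
  substr(mut, 5, 5) <- ifelse(substr(mut, 5, 5) == "A", "C", "A")
  substr(mut, 25, 25) <- ifelse(substr(mut, 25, 25) == "G", "T", "G")
  read_fwd <- paste0(random_dna(35, seed = 98), mut, random_dna(35, seed = 99))
  rs <- manual_read_set(c(read_fwd, revcomp_chr(read_fwd)), tag = "RSFD")
  res <- rsf_count(rs, tags)
  expect_equal(res$lx, 2)
})

test_that("more solo-LTRs never lower Rsf, and estimates track expectation", {
  # a light grid for the unit suite; the full five-point grid with deeper
  # pooling runs in the acceptance checks
  grid <- rsf_grid_benchmark(full = 100, solo_ratios = c(0, 2, 10),
                             reps = 15, seed = 5)
  expect_true(all(diff(grid$rsf) >= 0))
  expect_true(all(diff(grid$expected) > 0))
  expect_true(all(grid$rel_error < 0.30))
})

test_that("higher solo fractions in one species give it the higher Rsf", {
  tpl <- toy_ltr_template()
  tags <- extract_tags(tpl)
  gA <- build_genome(genome_spec(
    "SOLA", 1e6,
    list(list(template = tpl, copies = 150, solo_ltrs = 900,
              divergence = 0.01)), seed = 23))
  gB <- build_genome(genome_spec(
    "SOLB", 1e6,
    list(list(template = tpl, copies = 150, solo_ltrs = 150,
              divergence = 0.01)), seed = 24))
  wins <- vapply(1:12, function(r) {
    ra <- simulate_reads(gA, coverage = 0.3, insert_size = 300,
                         seed = 7000 + r, species_tag = "SOLA")
    rb <- simulate_reads(gB, coverage = 0.3, insert_size = 300,
                         seed = 8000 + r, species_tag = "SOLB")
    rsf_count(ra, tags)$rsf > rsf_count(rb, tags)$rsf
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
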