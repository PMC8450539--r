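# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_config <- function() cached("config", demo_config(seed = 1))

fixture_genomes <- function() cached("genomes", demo_genomes(fixture_config()))

fixture_templates <- function() cached("templates", default_templates())

fixture_reference <- function() cached("reference", mini_reference())

fixture_profiles <- function() {
  list(a = species_profile("toy small-genome species", "TOYA", 1.0),
       b = species_profile("toy large-genome species", "TOYB", 1.9))
}

# One preprocessed (quality-filtered, down-sampled to gp 0.015) read set
# per species, fixed seeds.
fixture_clean_reads <- function() {
  cached("clean_reads", {
    g <- fixture_genomes()
    p <- fixture_profiles()
    mk <- function(genome, profile, seed) {
      r <- simulate_reads(genome, coverage = 0.03, insert_size = 300,
                          seed = seed, species_tag = profile$code)
      suppressMessages(
        downsample_to_gp(quality_filter(r), profile, 0.015, seed = seed + 5))
    }
    list(a = mk(g$TOYA, p$a, 501), b = mk(g$TOYB, p$b, 601))
  })
}

fixture_comparative <- function() {
  cached("comparative", {
    clean <- fixture_clean_reads()
    cs <- comparative_cluster(list(clean$a, clean$b))
    ann <- annotate_clusters(cs, fixture_reference())
    list(cs = cs, ann = ann)
  })
}

# Quick manual read set: identical-length reads with uniform high quality.
manual_read_set <- function(seqs, tag = "TEST", qual_char = "G") {
  n <- length(seqs)
  stems <- sprintf("%s_%06d", tag, seq_len(ceiling(n / 2)))
  ids <- as.vector(rbind(paste0(stems, "/1"), paste0(stems, "/2")))[seq_len(n)]
  names(seqs) <- ids
  qual <- stats::setNames(strrep(qual_char, nchar(seqs)), ids)
  read_set(seqs, qual, tag)
}
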