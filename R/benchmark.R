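# Seeded benchmark experiments used by the test suite and the acceptance
# script. They run the package's own pipeline end to end on the two-species
# demo fixture and summarize how well truth is recovered.

#' Build the two demonstration genomes
#'
#' Materializes the two toy species of [demo_config()] (1.0 Mb and 1.9 Mb,
#' shared families at ~1.9x copy number, satellite at ~10% vs ~1%).
#'
#' @param config A [demo_config()]-style configuration.
#' @return Named list of [build_genome()] results keyed by species code.
#' @export
demo_genomes <- function(config = demo_config()) {
  templates <- default_templates(config$templates_seed %||% 1201L)
  out <- lapply(seq_along(config$species), function(i) {
    sp <- config$species[[i]]
    fams <- lapply(names(sp$families), function(f) {
      c(list(template = templates[[f]]), sp$families[[f]])
    })
    build_genome(genome_spec(sp$code, sp$target_size, fams,
                             seed = config$seed * 100L + i))
  })
  names(out) <- vapply(config$species, `[[`, "", "code")
  out
}

#' Genome-proportion recovery benchmark
#'
#' Repeats the full read chain (simulate at low coverage, quality-filter,
#' down-sample both species to an equal genome proportion, comparative
#' clustering, annotation) `reps` times with seeds derived from `seed`, and
#' compares the replicate-mean recovered genome proportion of every lineage
#' in every species against the genome truth tables. Replicate averaging is
#' deliberate: a single desk-scale sample holds only a few hundred reads,
#' so its binomial sampling error is of the same order as the tolerances of
#' interest; the mean over seeded replicates measures the estimator rather
#' than one draw's luck. The comparative scatter slope is estimated from
#' the replicate-pooled read counts of annotated non-satellite clusters
#' (the count-weighted through-origin fit, robust to the attenuation that
#' plain least squares suffers on small counts).
#'
#' @param genomes A [demo_genomes()] result (two species).
#' @param config The matching configuration.
#' @param reps Number of seeded replicates (default 30).
#' @param seed Base seed; replicate seeds are derived from it.
#' @return List: `gp` (data frame with lineage, species, truth and mean
#'   recovered GP in percent, and error in percentage points),
#'   `max_abs_error_pp`, `slope` (pooled), `expected_slope`,
#'   `reads_per_replicate`, `reps`.
#' @export
gp_recovery_benchmark <- function(genomes, config = demo_config(),
                                  reps = 30L, seed = 1L) {
  stopifnot(length(genomes) == 2L)
  codes <- names(genomes)
  profiles <- lapply(config$species, function(sp) {
    species_profile(sp$name, sp$code, sp$c_value_mb)
  })
  names(profiles) <- vapply(config$species, `[[`, "", "code")
  stopifnot(all(codes %in% names(profiles)))
  templates <- default_templates(config$templates_seed %||% 1201L)
  reference <- mini_reference(templates)
  rd <- config$reads %||% list()
  gp <- config$preprocess$target_gp %||% 0.015

  lineages <- sort_c(unique(genomes[[1L]]$truth$lineage))
  acc <- matrix(0, nrow = length(lineages), ncol = 2L,
                dimnames = list(lineages, codes))
  pooled_a <- pooled_b <- 0L
  n_analyzed <- c(0L, 0L)
  for (r in seq_len(reps)) {
    clean <- lapply(seq_along(codes), function(i) {
      s <- seed * 10000L + r * 10L + i
      reads <- simulate_reads(genomes[[i]],
                              coverage = rd$coverage %||% 0.03,
                              read_length = rd$read_length %||% 100L,
                              insert_size = rd$insert_size %||% 300L,
                              error_rate = rd$error_rate %||% 0.005,
                              seed = s, species_tag = codes[i])
      suppressMessages(downsample_to_gp(quality_filter(reads),
                                        profiles[[codes[i]]], gp,
                                        seed = s + 5L))
    })
    cs <- comparative_cluster(clean)
    ann <- annotate_clusters(cs, reference)
    la <- lineage_abundance(cs, ann)
    for (i in seq_along(codes)) {
      col <- paste0("gp_", codes[i])
      acc[, i] <- acc[, i] + vapply(lineages, function(lg) {
        sum(la[[col]][la$label == lg])
      }, numeric(1))
    }
    ct <- comparative_table(cs, ann, profiles[[codes[1L]]],
                            profiles[[codes[2L]]],
                            sampled_gp_a = gp, sampled_gp_b = gp)$records
    keep <- !(ct$lineage %in% c("satellite", "unclassified"))
    pooled_a <- pooled_a + sum(ct$reads_a[keep])
    pooled_b <- pooled_b + sum(ct$reads_b[keep])
    n_analyzed <- n_analyzed + cs$analyzed[codes]
  }
  est <- acc / reps
  truth <- vapply(seq_along(codes), function(i) {
    tt <- genomes[[i]]$truth
    vapply(lineages, function(lg) 100 * sum(tt$gp[tt$lineage == lg]),
           numeric(1))
  }, numeric(length(lineages)))
  gp_tab <- data.frame(
    lineage = rep(lineages, times = 2L),
    species = rep(codes, each = length(lineages)),
    truth_gp = as.vector(truth),
    recovered_gp = as.vector(est),
    error_pp = as.vector(est - truth),
    stringsAsFactors = FALSE)
  list(gp = gp_tab,
       max_abs_error_pp = max(abs(gp_tab$error_pp)),
       slope = pooled_b / pooled_a,
       expected_slope = profiles[[codes[2L]]]$c_value_mb /
         profiles[[codes[1L]]]$c_value_mb,
       reads_per_replicate = stats::setNames(n_analyzed / reps, codes),
       reps = reps)
}

#' Solo-LTR grid benchmark
#'
#' Builds a series of toy genomes holding full-length copies of one LTR
#' family fixed while increasing the solo-LTR count (solo:full ratios in
#' `solo_ratios`), samples reads at `coverage`, and pools Lx/LU tag counts
#' over `reps` seeded read replicates per genome. The estimated Rsf per
#' grid point is compared with the analytic expectation from exact
#' junction/LTR-end position counting ([rsf_expected()]).
#'
#' @param full Full-length copies per genome (default 100).
#' @param solo_ratios Solo:full ratios of the grid.
#' @param genome_size Toy genome length (default 1 Mb).
#' @param coverage Read coverage per replicate (default 0.1).
#' @param reps Read replicates pooled per grid point (default 20).
#' @param seed Base seed.
#' @return Data frame: `solo_ratio`, `lx`, `lu`, `rsf`, `expected`,
#'   `rel_error`.
#' @export
rsf_grid_benchmark <- function(full = 100L, solo_ratios = c(0, 1, 2, 5, 10),
                               genome_size = 1e6, coverage = 0.1,
                               reps = 20L, seed = 1L) {
  tpl <- with_seed(4242L, repeat_template(
    "GridLTR", "Ty1/copia-Angela",
    ltr = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = ""),
    internal = paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                     collapse = "")))
  tags <- extract_tags(tpl)
  rows <- lapply(seq_along(solo_ratios), function(k) {
    solo <- as.integer(round(solo_ratios[k] * full))
    g <- build_genome(genome_spec(
      "GRID", genome_size,
      list(list(template = tpl, copies = full, solo_ltrs = solo,
                divergence = 0)),
      seed = seed * 100L + k))
    lx <- lu <- 0L
    for (r in seq_len(reps)) {
      reads <- simulate_reads(g, coverage = coverage, insert_size = 300L,
                              error_rate = 0, seed = seed * 1000L + k * 37L + r,
                              species_tag = "GRID")
      res <- rsf_count(reads, tags)
      lx <- lx + res$lx
      lu <- lu + res$lu
    }
    expected <- rsf_expected(full, solo)
    est <- if (lu > 0) (lx - lu) / lu else NA_real_
    data.frame(solo_ratio = solo_ratios[k], lx = lx, lu = lu, rsf = est,
               expected = expected,
               rel_error = abs(est - expected) / expected)
  })
  do.call(rbind, rows)
}
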