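# Pipeline orchestration: a structured run configuration plus a staged
# driver that turns it into seeded, logged artifacts.

.config_keys <- list(
  top = c("seed", "templates_seed", "species", "organelle", "reads",
          "preprocess", "similarity", "annotation", "rsf", "ancestral"),
  species = c("name", "code", "c_value_mb", "target_size", "families"),
  family = c("copies", "solo_ltrs", "divergence", "monomers_per_copy"),
  organelle = c("fraction", "plastid_length", "mito_length"),
  reads = c("coverage", "read_length", "insert_size", "error_rate",
            "quality_low_rate"),
  preprocess = c("quality_threshold", "target_gp"),
  similarity = c("min_identity", "min_overlap_fraction", "kmer_seed_length",
                 "min_shared_kmers", "cluster_size_threshold",
                 "min_pair_links"),
  annotation = c("min_support", "min_identity", "min_overlap"),
  rsf = c("families", "max_mismatch", "min_junction_overhang"),
  ancestral = c("tree_file", "tip_file", "reference_node")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  }
}

#' Validate a pipeline run configuration
#'
#' Checks the nested key structure (unknown keys are rejected so typos
#' cannot silently disable a setting) and basic value sanity.
#'
#' @param config A run-configuration list (see [demo_config()]).
#' @return The config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  check_keys(config, .config_keys$top, "top level")
  stopifnot(is.numeric(config$seed), length(config$species) >= 1L)
  for (sp in config$species) {
    check_keys(sp, .config_keys$species, sprintf("species '%s'", sp$code))
    stopifnot(nchar(sp$code) == 4L, sp$c_value_mb > 0, sp$target_size > 0)
    for (fam in names(sp$families)) {
      check_keys(sp$families[[fam]], .config_keys$family,
                 sprintf("family '%s'", fam))
    }
  }
  for (blk in c("organelle", "reads", "preprocess", "similarity",
                "annotation", "rsf", "ancestral")) {
    if (!is.null(config[[blk]])) {
      check_keys(config[[blk]], .config_keys[[blk]], blk)
    }
  }
  codes <- vapply(config$species, `[[`, "", "code")
  if (anyDuplicated(codes)) stop("configuration error: duplicate species codes")
  invisible(config)
}

#' Demonstration run configuration
#'
#' A two-species toy setup mirroring the comparative study design: a 1.0 Mb
#' genome and a 1.9 Mb genome sharing the same repeat families at roughly
#' doubled copy number, plus a 26-bp tandem satellite at about 10% of the
#' large genome but only 1% of the small one, solo-LTRs of both LTR
#' lineages, and 5% organellar contamination. Genomes, element lengths and
#' read numbers are miniature (about 1/2500 of the real system) so the full
#' pipeline runs in minutes on one CPU while keeping the statistical
#' structure — equal sampled genome proportions, a near-twofold genome-size
#' ratio, and a satellite-driven size difference — intact.
#'
#' @param seed Global integer seed.
#' @return A validated run-configuration list.
#' @export
demo_config <- function(seed = 1L) {
  fam <- function(copies, solo_ltrs = 0L, divergence = 0.02,
                  monomers_per_copy = NULL) {
    out <- list(copies = copies, solo_ltrs = solo_ltrs,
                divergence = divergence)
    if (!is.null(monomers_per_copy)) out$monomers_per_copy <- monomers_per_copy
    out
  }
  config <- list(
    seed = as.integer(seed),
    templates_seed = 1201L,
    species = list(
      list(name = "toy small-genome species", code = "TOYA",
           c_value_mb = 1.0, target_size = 1000000L,
           families = list(
             angela  = fam(285L, solo_ltrs = 30L),
             retand  = fam(150L, solo_ltrs = 18L),
             tekay   = fam(110L),
             cacta   = fam(125L),
             rdna    = fam(17L),
             helosat = fam(38L, monomers_per_copy = 10L))),
      list(name = "toy large-genome species", code = "TOYB",
           c_value_mb = 1.9, target_size = 1900000L,
           families = list(
             angela  = fam(542L, solo_ltrs = 24L),
             retand  = fam(285L, solo_ltrs = 14L),
             tekay   = fam(209L),
             cacta   = fam(238L),
             rdna    = fam(32L),
             helosat = fam(731L, monomers_per_copy = 10L)))),
    organelle = list(fraction = 0.05, plastid_length = 15000L,
                     mito_length = 8000L),
    reads = list(coverage = 0.03, read_length = 100L, insert_size = 300L,
                 error_rate = 0.005, quality_low_rate = 0.001),
    preprocess = list(quality_threshold = 20L, target_gp = 0.015),
    similarity = list(),
    annotation = list(min_support = 0.10),
    rsf = list(families = c("angela", "retand"), max_mismatch = 2L,
               min_junction_overhang = 10L),
    ancestral = list(
      tree_file = system.file("extdata", "heloniadeae_toy_synthetic.nwk",
                              package = "skimrep"),
      tip_file = system.file("extdata", "heloniadeae_toy_tip_values.tsv",
                             package = "skimrep"),
      reference_node = "root")
  )
  validate_run_config(config)
  config
}

#' Write / read a run configuration as YAML
#' @param config A run-configuration list.
#' @param path YAML file path.
#' @return `path` (write) or the validated config (read).
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_run_config(config)
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

# TSV writer with a provenance header (version, seed, config hash) —
# deliberately free of timestamps so reruns are byte-identical.
write_stage_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# skimrep %s; seed=%d; config_md5=%s",
                     meta$version, meta$seed, meta$hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline stages
#'
#' Executes the requested stages in dependency order: `simulate`,
#' `preprocess`, `cluster`, `annotate`, `quantify`, `rsf`; `ancestral` is
#' independent and needs only the tree and tip-value files. Later stages
#' read the in-memory results of earlier ones, so a stage requested without
#' its upstream stage raises an error naming the stage to run first. All
#' randomness derives from `config$seed`; identical config and seed give
#' byte-identical artifacts. Every output TSV carries a header comment with
#' package version, seed and config hash, and a `run.log` records stage
#' progress.
#'
#' @param config A run configuration (see [demo_config()],
#'   [read_run_config()]).
#' @param outdir Output directory (created if needed).
#' @param stages Character subset of the stage names above.
#' @return Invisibly, a list with the in-memory stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "preprocess", "cluster",
                                    "annotate", "quantify", "rsf",
                                    "ancestral")) {
  validate_run_config(config)
  all_stages <- c("simulate", "preprocess", "cluster", "annotate",
                  "quantify", "rsf", "ancestral")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(version = as.character(utils::packageVersion("skimrep")),
               seed = as.integer(config$seed), hash = config_hash(config))
  logfile <- file.path(outdir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  need <- function(x, stage, upstream) {
    if (is.null(x)) {
      stop(sprintf("stage '%s' needs the output of stage '%s'; run it first",
                   stage, upstream))
    }
    x
  }
  st <- list()
  templates <- default_templates(config$templates_seed %||% 1201L)
  profiles <- lapply(config$species, function(sp) {
    species_profile(sp$name, sp$code, sp$c_value_mb)
  })
  names(profiles) <- vapply(config$species, `[[`, "", "code")

  if ("simulate" %in% stages) {
    say("stage simulate: %d species", length(config$species))
    rd <- config$reads %||% list()
    qm <- quality_model(low_rate = rd$quality_low_rate %||% 0.001)
    organelle <- make_organelle_reference(
      c(plastid_synthetic = config$organelle$plastid_length %||% 15000L,
        mito_synthetic = config$organelle$mito_length %||% 8000L))
    st$organelle_db <- organelle
    st$genomes <- list()
    st$raw_reads <- list()
    for (i in seq_along(config$species)) {
      sp <- config$species[[i]]
      fams <- lapply(names(sp$families), function(f) {
        c(list(template = templates[[f]]), sp$families[[f]])
      })
      spec <- genome_spec(sp$code, sp$target_size, fams,
                          seed = config$seed * 100L + i)
      genome <- build_genome(spec)
      reads <- simulate_reads(genome,
                              coverage = rd$coverage %||% 0.03,
                              read_length = rd$read_length %||% 100L,
                              insert_size = rd$insert_size %||% 300L,
                              error_rate = rd$error_rate %||% 0.005,
                              quality = qm,
                              seed = config$seed * 100L + 50L + i,
                              species_tag = sp$code)
      reads <- spike_organelle(reads, organelle,
                               fraction = config$organelle$fraction %||% 0,
                               insert_size = rd$insert_size %||% 300L,
                               quality = qm,
                               seed = config$seed * 100L + 70L + i)
      write_genome_fasta(genome,
                         file.path(outdir, paste0(sp$code, "_genome.fasta")))
      write_truth_table(genome,
                        file.path(outdir, paste0(sp$code, "_truth.tsv")))
      write_fastq(reads, file.path(outdir, paste0(sp$code, "_reads.fastq")))
      st$genomes[[sp$code]] <- genome
      st$raw_reads[[sp$code]] <- reads
      say("  %s: genome %d b, %d read pairs", sp$code, genome$length,
          n_pairs(reads))
    }
  }

  if ("preprocess" %in% stages) {
    raw <- need(st$raw_reads, "preprocess", "simulate")
    pp <- config$preprocess %||% list()
    st$clean_reads <- list()
    for (code in names(raw)) {
      r <- quality_filter(raw[[code]],
                          threshold = pp$quality_threshold %||% 20L)
      r <- filter_organellar(r, st$organelle_db)
      r <- downsample_to_gp(r, profiles[[code]],
                            target_gp = pp$target_gp %||% 0.015,
                            seed = config$seed * 100L + 90L +
                              match(code, names(raw)))
      write_fastq(r, file.path(outdir, paste0(code, "_clean.fastq")))
      write_interlaced_fasta(r, file.path(outdir,
                                          paste0(code, "_interlaced.fasta")))
      st$clean_reads[[code]] <- r
      say("  %s: %d/%d pairs retained after filtering + down-sampling",
          code, n_pairs(r), n_pairs(raw[[code]]))
    }
  }

  if ("cluster" %in% stages) {
    clean <- need(st$clean_reads, "cluster", "preprocess")
    sim <- config$similarity %||% list()
    params <- do.call(similarity_params, sim)
    st$clusters <- comparative_cluster(clean, params)
    st$superclusters <- link_superclusters(st$clusters)
    memb <- data.frame(read_id = names(st$clusters$membership),
                       cluster = ifelse(is.na(st$clusters$membership),
                                        "low/single-copy",
                                        st$clusters$membership),
                       stringsAsFactors = FALSE)
    write_stage_tsv(memb, file.path(outdir, "read_membership.tsv"), meta)
    say("  %d clusters, %d superclusters", nrow(st$clusters$clusters),
        length(unique(st$superclusters$supercluster)))
  }

  if ("annotate" %in% stages) {
    cs <- need(st$clusters, "annotate", "cluster")
    ann_cfg <- config$annotation %||% list()
    st$reference <- mini_reference(templates)
    st$annotation <- annotate_clusters(
      cs, st$reference,
      min_support = ann_cfg$min_support %||% 0.10,
      min_identity = ann_cfg$min_identity %||% 0.80,
      min_overlap = ann_cfg$min_overlap %||% 0.55)
    write_stage_tsv(st$annotation, file.path(outdir, "annotation.tsv"), meta)
    tab <- write_cluster_table(cs, file.path(outdir, "cluster_table.tsv"),
                               annotation = st$annotation,
                               superclusters = st$superclusters)
    write_stage_tsv(tab, file.path(outdir, "cluster_table.tsv"), meta)
    consensi <- vapply(cs$clusters$id, function(id) {
      cluster_consensus(cs, id)
    }, character(1))
    x <- Biostrings::DNAStringSet(consensi)
    names(x) <- cs$clusters$id
    Biostrings::writeXStringSet(x, file.path(outdir, "consensus.fasta"))
    say("  annotated %d clusters", nrow(st$annotation))
  }

  if ("quantify" %in% stages) {
    cs <- need(st$clusters, "quantify", "cluster")
    ann <- need(st$annotation, "quantify", "annotate")
    codes <- names(profiles)
    st$abundance <- abundance_table(cs, ann, profiles)
    write_stage_tsv(st$abundance, file.path(outdir, "abundance.tsv"), meta)
    if (length(codes) == 2L) {
      gp <- config$preprocess$target_gp %||% 0.015
      st$comparative <- comparative_table(cs, ann, profiles[[1L]],
                                          profiles[[2L]],
                                          sampled_gp_a = gp,
                                          sampled_gp_b = gp)
      write_stage_tsv(st$comparative$records,
                      file.path(outdir, "comparative.tsv"), meta)
      st$slope <- scatter_slope(st$comparative)
      regs <- lineage_regressions(st$comparative)
      if (!is.null(regs)) {
        write_stage_tsv(regs, file.path(outdir, "regressions.tsv"), meta)
      }
      say("  scatter slope %.3f (expected %.3f)", st$slope,
          st$comparative$expected_slope)
    }
  }

  if ("rsf" %in% stages) {
    raw <- need(st$raw_reads, "rsf", "simulate")
    rsf_cfg <- config$rsf %||% list(families = character(0))
    rows <- list()
    for (code in names(raw)) {
      clean <- quality_filter(raw[[code]])
      for (f in rsf_cfg$families) {
        tags <- extract_tags(templates[[f]])
        res <- rsf_count(clean, tags,
                         max_mismatch = rsf_cfg$max_mismatch %||% 2L,
                         min_junction_overhang =
                           rsf_cfg$min_junction_overhang %||% 10L,
                         species = code)
        rows[[paste(code, f)]] <- data.frame(
          family = res$family, species = code, lx = res$lx, lu = res$lu,
          rsf = res$rsf, stringsAsFactors = FALSE)
      }
    }
    st$rsf <- do.call(rbind, rows)
    if (!is.null(st$rsf)) {
      write_stage_tsv(st$rsf, file.path(outdir, "rsf.tsv"), meta)
    }
    say("  Rsf computed for %d family x species combinations",
        length(rows))
  }

  if ("ancestral" %in% stages) {
    anc <- config$ancestral
    if (is.null(anc$tree_file) || !nzchar(anc$tree_file)) {
      stop("stage 'ancestral' needs ancestral$tree_file in the config")
    }
    tree <- ape::read.tree(anc$tree_file)
    tips <- read_tip_values(anc$tip_file)
    st$ancestral <- ml_ancestral_bm(tree, tips)
    deltas <- branch_deltas(st$ancestral, anc$reference_node %||% "root")
    out <- st$ancestral$nodes
    out$delta <- NA_real_
    out$delta[out$is_tip] <- deltas[out$label[out$is_tip]]
    write_stage_tsv(out, file.path(outdir, "ancestral.tsv"), meta)
    say("  ancestral reconstruction over %d tips; sigma^2 = %.4g",
        sum(out$is_tip), st$ancestral$sigma_squared)
  }

  writeLines(log_lines, logfile)
  invisible(c(st, list(profiles = profiles, meta = meta, outdir = outdir)))
}
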