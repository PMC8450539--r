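#' Specify a synthetic genome
#'
#' Describes one species' miniature genome: target size, the repeat families
#' it carries (template, copy number, solo-LTR count, per-copy divergence),
#' and the seed that makes the build reproducible. The remainder of the
#' genome is random single-copy background.
#'
#' @param species_name Species identifier.
#' @param target_size Genome length in bases.
#' @param families List of family entries, each a list with elements
#'   `template` (a [repeat_template()]), `copies` (count of full copies),
#'   `solo_ltrs` (solo-LTR insertions, LTR templates only; default 0),
#'   `divergence` (per-copy substitution fraction; default 0.02) and, for
#'   satellites, `monomers_per_copy` (tandem monomers per placed array;
#'   default 10).
#' @param seed Integer seed.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(species_name, target_size, families, seed = 1L) {
  stopifnot(is.character(species_name), target_size > 0)
  total <- 0
  for (f in families) {
    stopifnot(inherits(f$template, "repeat_template"))
    copies <- f$copies %||% 0L
    solo <- f$solo_ltrs %||% 0L
    div <- f$divergence %||% 0.02
    if (copies < 0 || solo < 0) stop("copy counts must be non-negative")
    if (div < 0 || div >= 1) stop("divergence must be in [0, 1)")
    if (solo > 0 && !is_ltr_template(f$template)) {
      stop(sprintf("family '%s': solo_ltr_count must be 0 for non-LTR templates",
                   f$template$name))
    }
    unit <- if (f$template$kind == "satellite") {
      (f$monomers_per_copy %||% 10L) * f$template$monomer_length
    } else {
      template_length(f$template)
    }
    fam_bases <- copies * unit +
      if (solo > 0) solo * nchar(ltr_segment(f$template)) else 0
    total <- total + fam_bases
    if (total > target_size) {
      stop(sprintf("capacity error: requested copies of family '%s' exceed the %d b target size",
                   f$template$name, as.integer(target_size)))
    }
  }
  structure(list(species_name = species_name,
                 target_size = as.integer(target_size),
                 families = families, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Build a synthetic genome from a specification
#'
#' Places mutated copies of each family at uniformly drawn non-overlapping
#' positions on a random single-copy background (overlapping draws are
#' rejected and re-drawn). Full LTR-element copies carry both LTRs and the
#' internal region; solo-LTR insertions consist of exactly one LTR segment.
#' Satellite copies are tandem arrays of the monomer. Each placed copy is
#' independently mutated at the family's substitution fraction. The build is
#' deterministic for a fixed spec seed.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `simulated_genome` with elements `sequence`
#'   (character), `length`, `intervals` (one row per placed copy: start, end,
#'   family, lineage, kind in full/solo/array) and `truth` (per-family totals:
#'   copies, solo_ltrs, bases, gp where gp is bases occupied / genome length).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    g <- spec$target_size
    # Expand the family list into one entry per placed copy.
    units <- list()
    for (f in spec$families) {
      tpl <- f$template
      copies <- f$copies %||% 0L
      solo <- f$solo_ltrs %||% 0L
      div <- f$divergence %||% 0.02
      if (copies > 0) {
        base_seq <- if (tpl$kind == "satellite") {
          strrep(tpl$segments[[1]]$seq, f$monomers_per_copy %||% 10L)
        } else {
          paste(vapply(tpl$segments, `[[`, "", "seq"), collapse = "")
        }
        kind <- if (tpl$kind == "satellite") "array" else "full"
        for (i in seq_len(copies)) {
          units[[length(units) + 1L]] <- list(
            family = tpl$name, lineage = tpl$lineage, kind = kind,
            seq = mutate_sequence(base_seq, div))
        }
      }
      if (solo > 0) {
        for (i in seq_len(solo)) {
          units[[length(units) + 1L]] <- list(
            family = tpl$name, lineage = tpl$lineage, kind = "solo",
            seq = mutate_sequence(ltr_segment(tpl), div))
        }
      }
    }
    lens <- vapply(units, function(u) nchar(u$seq), integer(1))
    if (sum(lens) > g) stop("capacity error: families exceed target size")

    # Uniform non-overlapping placement by rejection sampling, longest first
    # to keep the rejection rate low.
    ord <- order(lens, decreasing = TRUE)
    starts <- integer(length(units))
    ends <- integer(length(units))
    acc_s <- integer(0)
    acc_e <- integer(0)
    for (i in ord) {
      len <- lens[i]
      placed <- FALSE
      for (try in seq_len(10000L)) {
        s <- sample.int(g - len + 1L, 1L)
        e <- s + len - 1L
        if (!any(s <= acc_e & e >= acc_s)) {
          starts[i] <- s; ends[i] <- e
          acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place a copy of family '%s' without overlap; lower the repeat density",
                     units[[i]]$family))
      }
    }

    # Assemble: background gaps interleaved with the placed copies.
    background <- random_dna(g)
    o <- order(starts)
    gap_start <- c(1L, ends[o] + 1L)
    gap_end <- c(starts[o] - 1L, g)
    gaps <- ifelse(gap_start <= gap_end,
                   substring(background, gap_start, gap_end), "")
    copy_seqs <- vapply(units[o], `[[`, "", "seq")
    sequence <- paste0(paste0(gaps[seq_along(copy_seqs)], copy_seqs,
                              collapse = ""), gaps[length(gaps)])
    stopifnot(nchar(sequence) == g)

    intervals <- data.frame(
      start = starts[o], end = ends[o],
      family = vapply(units[o], `[[`, "", "family"),
      lineage = vapply(units[o], `[[`, "", "lineage"),
      kind = vapply(units[o], `[[`, "", "kind"),
      stringsAsFactors = FALSE)

    truth <- do.call(rbind, lapply(spec$families, function(f) {
      rows <- intervals$family == f$template$name
      bases <- sum(intervals$end[rows] - intervals$start[rows] + 1L)
      data.frame(family = f$template$name, lineage = f$template$lineage,
                 copies = f$copies %||% 0L, solo_ltrs = f$solo_ltrs %||% 0L,
                 bases = bases, gp = bases / g, stringsAsFactors = FALSE)
    }))

    structure(list(sequence = sequence, length = g, intervals = intervals,
                   truth = truth, spec = spec),
              class = "simulated_genome")
  })
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf("<simulated_genome> %s: %d b, %d placed copies, repeat fraction %.1f%%\n",
              x$spec$species_name, x$length, nrow(x$intervals),
              100 * sum(x$truth$bases) / x$length))
  invisible(x)
}

#' Write a simulated genome as FASTA
#' @param genome A [build_genome()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$spec$species_name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a genome truth table as TSV
#'
#' One row per family: copies, solo-LTRs, bases occupied and true genome
#' proportion.
#' @inheritParams write_genome_fasta
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(genome, path) {
  utils::write.table(genome$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
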