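#' Build a mini repeat reference
#'
#' A compact lineage-labelled exemplar set for cluster classification:
#' one exemplar per simulator template (the full element, or a short tandem
#' array for satellites) plus random decoy entries carrying unrelated
#' lineage labels. A full curated retrotransposon-domain database is out of
#' scope at desk scale; this mini reference plays its role behind the same
#' interface.
#'
#' @param templates Named list of [repeat_template()] objects
#'   (default [default_templates()]).
#' @param decoy_lineages Lineage labels for random decoy exemplars.
#' @param decoy_length Decoy sequence length.
#' @param seed Integer seed for the decoys.
#' @return Data frame with class `repeat_reference`: `name`, `lineage`,
#'   `sequence`.
#' @export
mini_reference <- function(templates = default_templates(),
                           decoy_lineages = c("Ty3/gypsy-Athila",
                                              "Ty1/copia-TAR",
                                              "Pararetrovirus"),
                           decoy_length = 400L, seed = 911L) {
  ex <- lapply(templates, function(tpl) {
    seqc <- if (tpl$kind == "satellite") {
      strrep(tpl$segments[[1]]$seq, max(2L, ceiling(200 / tpl$monomer_length)))
    } else {
      paste(vapply(tpl$segments, `[[`, "", "seq"), collapse = "")
    }
    data.frame(name = tpl$name, lineage = tpl$lineage, sequence = seqc,
               stringsAsFactors = FALSE)
  })
  dec <- with_seed(seed, lapply(seq_along(decoy_lineages), function(i) {
    data.frame(name = sprintf("decoy%d", i), lineage = decoy_lineages[i],
               sequence = paste(sample(c("A", "C", "G", "T"), decoy_length,
                                       replace = TRUE), collapse = ""),
               stringsAsFactors = FALSE)
  }))
  ref <- do.call(rbind, c(ex, dec))
  if (anyDuplicated(ref$name)) stop("reference exemplar names must be unique")
  class(ref) <- c("repeat_reference", "data.frame")
  ref
}

#' Write a repeat reference as FASTA
#'
#' The lineage travels in the description line as `lineage=<label>`.
#' @param reference A [mini_reference()]-style data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$sequence)
  names(x) <- sprintf("%s lineage=%s", reference$name, reference$lineage)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a lineage-labelled reference FASTA
#' @param path FASTA with `lineage=<label>` in the description lines.
#' @return A `repeat_reference` data frame.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  lineage <- sub(".*lineage=([^ ]+).*", "\\1", names(x))
  if (any(lineage == names(x))) {
    stop("reference FASTA descriptions must carry lineage=<label>")
  }
  ref <- data.frame(name = sub(" .*", "", names(x)), lineage = lineage,
                    sequence = as.character(x), stringsAsFactors = FALSE)
  class(ref) <- c("repeat_reference", "data.frame")
  ref
}

# Read-level lineage hits: logical matrix (reads x lineages). A read hits a
# lineage when it has a strand-aware local alignment to any exemplar of that
# lineage with identity >= min_identity over >= min_overlap of the read.
read_lineage_hits <- function(seqs, reference, min_identity = 0.80,
                              min_overlap = 0.55) {
  lineages <- sort_c(unique(reference$lineage))
  hits <- matrix(FALSE, nrow = length(seqs), ncol = length(lineages),
                 dimnames = list(names(seqs), lineages))
  if (!length(seqs)) return(hits)
  need <- span_needed(min_overlap, nchar(seqs[[1]]))
  for (r in seq_len(nrow(reference))) {
    lg <- reference$lineage[r]
    todo <- which(!hits[, lg])
    if (!length(todo)) next
    for (subj in c(reference$sequence[r], revcomp_chr(reference$sequence[r]))) {
      left <- todo[!hits[todo, lg]]
      if (!length(left)) break
      a <- align_local(seqs[left], subj)
      hits[left, lg] <- a$identity >= min_identity & a$cols >= need
    }
  }
  hits
}

# Pick winner and runner-up lineages from a support vector (fractions);
# ties broken by the lexicographically smaller label.
pick_winner <- function(support) {
  ord <- order(-support, names(support), method = "radix")
  list(label = names(support)[ord[1]], support = support[[ord[1]]],
       runner_up = if (length(support) > 1L) names(support)[ord[2]] else NA_character_,
       runner_support = if (length(support) > 1L) support[[ord[2]]] else NA_real_)
}

#' Classify one cluster against a repeat reference
#'
#' Searches each cluster read against the lineage exemplars; the winning
#' lineage is the one hitting the largest fraction of reads (support), with
#' exact ties broken deterministically toward the lexicographically smaller
#' label. Clusters whose best support falls below `min_support` are left
#' `"unclassified"`.
#'
#' @param cs A `cluster_set`.
#' @param id Cluster id.
#' @param reference A `repeat_reference`.
#' @param min_support Minimum winning support (default 0.10).
#' @param min_identity,min_overlap Read-vs-exemplar hit thresholds.
#' @return List: `id`, `label`, `support`, `runner_up`, `runner_support`.
#' @export
classify_cluster <- function(cs, id, reference, min_support = 0.10,
                             min_identity = 0.80, min_overlap = 0.55) {
  if (!nrow(reference)) stop("empty reference")
  members <- cluster_members(cs, id)
  stopifnot(length(members) >= 1L)
  hits <- read_lineage_hits(cs$reads$seq[members], reference,
                            min_identity, min_overlap)
  support <- colMeans(hits)
  w <- pick_winner(support)
  label <- if (w$support >= min_support) w$label else "unclassified"
  list(id = id, label = label, support = w$support,
       runner_up = w$runner_up, runner_support = w$runner_support)
}

#' Detect a tandem-repeat monomer in a consensus
#'
#' Returns the smallest period `p <= max_monomer` at which the consensus
#' aligns to itself shifted by `p` with identity at least `min_identity`
#' over at least `min_copies * p` bases, or `NA` when no period qualifies.
#'
#' @param consensus Consensus sequence (character).
#' @param min_copies Minimum monomer copies the periodicity must span
#'   (default 2).
#' @param max_monomer Largest monomer length to consider (default 50).
#' @param min_identity Shift self-identity threshold (default 0.80).
#' @return Integer monomer length, or `NA_integer_`.
#' @export
detect_satellite <- function(consensus, min_copies = 2L, max_monomer = 50L,
                             min_identity = 0.80) {
  n <- nchar(consensus)
  ch <- charToRaw(consensus)
  for (p in seq_len(max_monomer)) {
    span <- n - p
    if (span < min_copies * p) break
    ident <- sum(ch[seq_len(span)] == ch[seq_len(span) + p]) / span
    if (ident >= min_identity) return(as.integer(p))
  }
  NA_integer_
}

#' Annotate all clusters of a clustering run
#'
#' Classifies every cluster against the reference (reads are searched once
#' and aggregated per cluster) and runs tandem-satellite detection on each
#' cluster consensus; a detected monomer overrides the mobile-element label
#' with `"satellite"`.
#'
#' @inheritParams classify_cluster
#' @param satellite_override Run [detect_satellite()] on consensi and
#'   relabel hits as satellite (default `TRUE`).
#' @return Data frame: `id`, `label`, `support`, `runner_up`,
#'   `runner_support`, `monomer`.
#' @export
annotate_clusters <- function(cs, reference, min_support = 0.10,
                              min_identity = 0.80, min_overlap = 0.55,
                              satellite_override = TRUE) {
  if (!nrow(reference)) stop("empty reference")
  ids <- cs$clusters$id
  if (!length(ids)) {
    return(data.frame(id = character(0), label = character(0),
                      support = numeric(0), runner_up = character(0),
                      runner_support = numeric(0), monomer = integer(0)))
  }
  clustered <- !is.na(cs$membership)
  hits <- read_lineage_hits(cs$reads$seq[names(cs$membership)[clustered]],
                            reference, min_identity, min_overlap)
  memb <- cs$membership[clustered]
  out <- do.call(rbind, lapply(ids, function(id) {
    support <- colMeans(hits[memb == id, , drop = FALSE])
    w <- pick_winner(support)
    label <- if (w$support >= min_support) w$label else "unclassified"
    data.frame(id = id, label = label, support = w$support,
               runner_up = w$runner_up, runner_support = w$runner_support,
               monomer = NA_integer_, stringsAsFactors = FALSE)
  }))
  if (satellite_override) {
    for (r in seq_len(nrow(out))) {
      p <- detect_satellite(cluster_consensus(cs, out$id[r]))
      if (!is.na(p)) {
        out$monomer[r] <- p
        out$label[r] <- "satellite"
      }
    }
  }
  out
}
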