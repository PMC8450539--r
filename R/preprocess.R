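#' Species profile
#'
#' Metadata for one sequenced species: display name, four-letter prefix code
#' used to tag its reads, and its 1C genome size in megabases.
#'
#' @param species_name Species name.
#' @param code Four-letter prefix code.
#' @param c_value_mb 1C-value in Mb; must be > 0.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(species_name, code, c_value_mb) {
  stopifnot(nchar(code) == 4L, c_value_mb > 0)
  structure(list(species_name = species_name, code = code,
                 c_value_mb = c_value_mb), class = "species_profile")
}

#' Preprocessing parameters
#'
#' @param quality_threshold Phred score every base of a retained pair must
#'   reach (default 20).
#' @param quality_mode `"full_length"` requires every base of both mates to
#'   reach the threshold; `"mean"` requires the mean per mate.
#' @param organelle_min_identity Minimum alignment identity for an
#'   organelle hit.
#' @param organelle_min_overlap Minimum aligned fraction of the read for an
#'   organelle hit.
#' @param target_gp Genome proportion the down-sampled reads should
#'   represent (0.015 for individual runs, 0.013 for comparative runs).
#' @param read_length Read length in bases.
#' @param seed Integer seed for down-sampling.
#' @return A list with class `preprocess_config`.
#' @export
preprocess_config <- function(quality_threshold = 20L,
                              quality_mode = c("full_length", "mean"),
                              organelle_min_identity = 0.90,
                              organelle_min_overlap = 0.80,
                              target_gp = 0.015,
                              read_length = 100L,
                              seed = 1L) {
  stopifnot(quality_threshold >= 0,
            organelle_min_identity > 0, organelle_min_identity <= 1,
            organelle_min_overlap > 0, organelle_min_overlap <= 1,
            target_gp > 0, target_gp <= 1)
  structure(list(quality_threshold = as.integer(quality_threshold),
                 quality_mode = match.arg(quality_mode),
                 organelle_min_identity = organelle_min_identity,
                 organelle_min_overlap = organelle_min_overlap,
                 target_gp = target_gp,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Quality-filter read pairs
#'
#' Retains a pair only when both mates satisfy the quality criterion over
#' the full read: in the default `"full_length"` mode every single base must
#' reach the threshold; in `"mean"` mode the mean quality per mate must.
#' Retained reads are returned unchanged, so the filter is idempotent.
#'
#' @param reads A [read_set()] with qualities.
#' @param threshold Phred threshold (default 20).
#' @param mode `"full_length"` (default) or `"mean"`.
#' @return The filtered [read_set()].
#' @export
quality_filter <- function(reads, threshold = 20L,
                           mode = c("full_length", "mean")) {
  stopifnot(inherits(reads, "read_set"))
  mode <- match.arg(mode)
  if (!length(reads$seq)) return(reads)
  if (any(!nzchar(reads$qual)) || anyNA(reads$qual)) {
    stop("format error: reads are missing per-base qualities")
  }
  stat <- vapply(reads$qual, function(q) {
    v <- phred_to_int(q)
    if (mode == "full_length") min(v) else mean(v)
  }, numeric(1))
  ok_read <- stat >= threshold
  stems <- pair_stem(names(reads$seq))
  ok_pair <- tapply(ok_read, stems, all)
  subset_pairs(reads, names(ok_pair)[ok_pair])
}

# Logical per read: does it match any database sequence with at least
# min_identity over min_overlap of the read length (strand-aware local
# alignment, k-mer seeded)?
organelle_hits <- function(seqs, db, min_identity, min_overlap, k = 13L) {
  db_kmers <- unique(unlist(lapply(db, canonical_kmers, k = k)))
  cand <- vapply(seqs, function(s) {
    any(canonical_kmers(s, k) %in% db_kmers)
  }, logical(1))
  hit <- logical(length(seqs))
  if (!any(cand)) return(hit)
  idx <- which(cand)
  L <- nchar(seqs[idx[1]])
  need <- span_needed(min_overlap, L)
  for (d in db) {
    todo <- idx[!hit[idx]]
    if (!length(todo)) break
    for (subj in c(d, revcomp_chr(d))) {
      todo2 <- todo[!hit[todo]]
      if (!length(todo2)) break
      a <- align_local(seqs[todo2], subj)
      hit[todo2] <- hit[todo2] |
        (a$identity >= min_identity & a$cols >= need)
    }
  }
  hit
}

#' Remove read pairs of organellar origin
#'
#' A pair is removed when either mate has a strand-aware local match to any
#' database sequence with at least `min_identity` over at least
#' `min_overlap` of the read length. Matching is seeded with shared
#' canonical 13-mers, so unrelated reads are never aligned. The reads that
#' remain are considered to be of nuclear origin; retained reads are
#' unchanged (the filter is idempotent).
#'
#' @param reads A [read_set()].
#' @param organelle_db Named character vector of organelle sequences.
#' @param min_identity Minimum alignment identity (default 0.90).
#' @param min_overlap Minimum aligned fraction of the read (default 0.80).
#' @return The filtered [read_set()].
#' @export
filter_organellar <- function(reads, organelle_db, min_identity = 0.90,
                              min_overlap = 0.80) {
  stopifnot(inherits(reads, "read_set"))
  if (!length(organelle_db)) stop("organelle_db must be non-empty")
  if (!length(reads$seq)) return(reads)
  hit <- organelle_hits(reads$seq, organelle_db, min_identity, min_overlap)
  stems <- pair_stem(names(reads$seq))
  bad <- tapply(hit, stems, any)
  subset_pairs(reads, names(bad)[!bad])
}

#' Read budget for a target genome proportion
#'
#' Number of reads whose total bases represent `target_gp` of a genome of
#' `c_value_mb` megabases at the given read length:
#' `round(target_gp * c_value_mb * 1e6 / read_length)`.
#'
#' @param target_gp Genome proportion, e.g. 0.015.
#' @param c_value_mb 1C-value in Mb.
#' @param read_length Read length in bases.
#' @return Integer read count.
#' @examples
#' gp_read_budget(0.015, 2480)  # 372000
#' @export
gp_read_budget <- function(target_gp, c_value_mb, read_length = 100L) {
  stopifnot(target_gp > 0, c_value_mb > 0, read_length > 0)
  as.integer(round(target_gp * c_value_mb * 1e6 / read_length))
}

#' Down-sample reads to a target genome proportion
#'
#' Uniformly samples pairs without replacement until the read count matches
#' the species' [gp_read_budget()] (odd budgets are rounded down to an even
#' read count so mates stay together). Deterministic per seed; the output is
#' a subset of the input in the input's order.
#'
#' @param reads A [read_set()].
#' @param profile A [species_profile()] providing the 1C-value.
#' @param target_gp Genome proportion to sample (e.g. 0.015).
#' @param seed Integer seed.
#' @return The down-sampled [read_set()].
#' @export
downsample_to_gp <- function(reads, profile, target_gp, seed = 1L) {
  stopifnot(inherits(reads, "read_set"), inherits(profile, "species_profile"))
  n_reads <- gp_read_budget(target_gp, profile$c_value_mb, reads$read_length)
  need_pairs <- n_reads %/% 2L
  stems <- unique(pair_stem(names(reads$seq)))
  if (length(stems) < need_pairs) {
    stop(sprintf("insufficient reads: %d pairs available, %d required",
                 length(stems), need_pairs))
  }
  keep <- with_seed(seed, sample(stems, need_pairs))
  message(sprintf("down-sampled %s to %d reads (%d pairs, gp %.4f of %s Mb)",
                  profile$code, 2L * need_pairs, need_pairs, target_gp,
                  format(profile$c_value_mb)))
  subset_pairs(reads, keep)
}
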