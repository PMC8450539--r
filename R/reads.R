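#' Construct a paired-end read set
#'
#' Container for quality-bearing paired reads. Reads are stored in mate
#' order (`id/1`, `id/2`), all with identical length. `provenance` maps each
#' pair stem to the repeat family the fragment was simulated from (or
#' `"single-copy"`, `"organelle"`, `"ambiguous"`) when known.
#'
#' @param seq Named character vector of read sequences; names are read ids
#'   ending in `/1` or `/2` and beginning with the four-letter species code.
#' @param qual Named character vector of Phred+33 quality strings, parallel
#'   to `seq`.
#' @param species_tag Four-letter species code.
#' @param read_length Common read length in bases.
#' @param provenance Optional named character vector keyed by pair stem.
#' @return An object of class `read_set`.
#' @export
read_set <- function(seq, qual, species_tag, read_length = NULL,
                     provenance = NULL) {
  stopifnot(length(seq) == length(qual),
            identical(names(seq), names(qual)))
  if (length(seq)) {
    if (is.null(read_length)) read_length <- nchar(seq[[1]])
    if (any(nchar(seq) != read_length)) {
      stop("all reads must have identical read_length")
    }
    if (any(nchar(qual) != read_length)) {
      stop("quality strings must match read_length")
    }
    if (!all(grepl("/[12]$", names(seq)))) {
      stop("read ids must carry /1 or /2 mate suffixes")
    }
  }
  if (!is.na(species_tag) && nchar(species_tag) != 4L) {
    stop("species_tag must be a 4-character code")
  }
  structure(list(seq = seq, qual = qual, species_tag = species_tag,
                 read_length = as.integer(read_length %||% 0L),
                 provenance = provenance),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s: %d reads (%d pairs) of %d b\n",
              x$species_tag, length(x$seq), n_pairs(x), x$read_length))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$seq)

#' Number of read pairs in a read set
#' @param reads A [read_set()].
#' @return Integer pair count.
#' @export
n_pairs <- function(reads) length(unique(pair_stem(names(reads$seq))))

# Subset a read set by pair stems, keeping mates together and input order.
subset_pairs <- function(reads, stems) {
  keep <- pair_stem(names(reads$seq)) %in% stems
  read_set(reads$seq[keep], reads$qual[keep], reads$species_tag,
           reads$read_length,
           provenance = reads$provenance[names(reads$provenance) %in% stems])
}

# Apply i.i.d. per-base substitution errors to a character vector of reads.
apply_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  L <- nchar(reads[[1]])
  nerr <- stats::rbinom(length(reads), L, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    pos <- sample.int(L, nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(bases[bases != old], 1L)
    }
  }
  reads
}

#' Two-state sequencing quality model
#'
#' Most bases receive the high quality score; each base is independently
#' error-prone (low quality) with probability `low_rate`. This is the
#' simplest model that exercises a full-length Phred-20 read filter.
#'
#' @param high,low Phred scores of the two states.
#' @param low_rate Per-base probability of the low-quality state.
#' @return A list with class `quality_model`.
#' @export
quality_model <- function(high = 38L, low = 12L, low_rate = 0.001) {
  stopifnot(high >= 0, low >= 0, low_rate >= 0, low_rate < 1)
  structure(list(high = as.integer(high), low = as.integer(low),
                 low_rate = low_rate), class = "quality_model")
}

# Draw quality strings for n reads of length L under a quality_model.
draw_qualities <- function(n, L, model) {
  hi <- rawToChar(as.raw(model$high + 33L))
  lo <- rawToChar(as.raw(model$low + 33L))
  q <- rep(strrep(hi, L), n)
  if (model$low_rate > 0 && n > 0) {
    nlow <- stats::rbinom(n, L, model$low_rate)
    for (i in which(nlow > 0L)) {
      for (p in sample.int(L, nlow[i])) substr(q[i], p, p) <- lo
    }
  }
  q
}

# Majority-overlap provenance of fragments against truth intervals.
# Ties between a repeat family and the background (or between two families)
# are labelled "ambiguous"; background-majority fragments are "single-copy".
fragment_provenance <- function(starts, insert, intervals, genome_len) {
  n <- length(starts)
  out <- character(n)
  iv_s <- intervals$start
  iv_e <- intervals$end
  fam <- intervals$family
  for (i in seq_len(n)) {
    s <- starts[i]
    e <- s + insert - 1L
    lo <- findInterval(s - 1L, iv_e) + 1L
    hi <- findInterval(e, iv_s)
    if (lo > hi) {
      out[i] <- "single-copy"
      next
    }
    idx <- lo:hi
    ov <- pmin(iv_e[idx], e) - pmax(iv_s[idx], s) + 1L
    by_fam <- tapply(ov, fam[idx], sum)
    bg <- insert - sum(ov)
    all_ov <- c(by_fam, "single-copy" = bg)
    top <- max(all_ov)
    winners <- names(all_ov)[all_ov == top]
    out[i] <- if (length(winners) > 1L) "ambiguous" else winners
  }
  out
}

#' Simulate paired-end reads from a genome
#'
#' Draws `round(coverage * genome length / (2 * read_length))` fragments with
#' uniform start positions; the first mate is the leading `read_length` bases
#' of the fragment and the second mate is the reverse complement of its
#' trailing bases. Per-base substitution errors are applied at `error_rate`
#' and qualities drawn from the [quality_model()]. Pair provenance is the
#' majority-overlap family of the fragment against the genome truth
#' intervals.
#'
#' @param genome A [build_genome()] result.
#' @param coverage Fraction of 1C to sample (e.g. 0.15); must be > 0.
#' @param read_length Read length in bases (default 100).
#' @param insert_size Fragment length; must be at least `2 * read_length`.
#' @param error_rate Per-base substitution error fraction.
#' @param quality A [quality_model()].
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param species_tag Four-letter read-id prefix; defaults to the first
#'   four letters of the species name, upper-cased.
#' @return A [read_set()].
#' @export
simulate_reads <- function(genome, coverage, read_length = 100L,
                           insert_size = 500L, error_rate = 0.005,
                           quality = quality_model(), seed = 1L,
                           species_tag = NULL) {
  stopifnot(inherits(genome, "simulated_genome"))
  if (coverage <= 0) stop("coverage must be > 0")
  if (insert_size < 2L * read_length) {
    stop("insert_size must be at least 2 * read_length")
  }
  g <- genome$length
  npair <- round(coverage * g / (2 * read_length))
  tag <- species_tag %||%
    toupper(substr(gsub("[^A-Za-z]", "", genome$spec$species_name), 1, 4))
  if (nchar(tag) != 4L) stop("species_tag must be a 4-character code")
  with_seed(seed, {
    starts <- sample.int(g - insert_size + 1L, npair, replace = TRUE)
    r1 <- substring(genome$sequence, starts, starts + read_length - 1L)
    r2 <- revcomp_chr(substring(genome$sequence,
                                starts + insert_size - read_length,
                                starts + insert_size - 1L))
    stems <- sprintf("%s_%06d", tag, seq_len(npair))
    seq <- apply_errors(as.vector(rbind(r1, r2)), error_rate)
    names(seq) <- as.vector(rbind(paste0(stems, "/1"), paste0(stems, "/2")))
    qual <- stats::setNames(draw_qualities(2L * npair, read_length, quality),
                            names(seq))
    prov <- stats::setNames(
      fragment_provenance(starts, insert_size, genome$intervals, g), stems)
    read_set(seq, qual, tag, read_length, provenance = prov)
  })
}

#' Synthetic organelle reference sequences
#'
#' Random stand-ins for plastid and mitochondrial genomes, used to spike
#' organellar contamination into simulated read sets and as the database for
#' [filter_organellar()]. These are synthetic sequences, not real organelle
#' genomes.
#'
#' @param lengths Named integer vector of sequence lengths.
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
make_organelle_reference <- function(lengths = c(plastid_synthetic = 15000L,
                                                 mito_synthetic = 8000L),
                                     seed = 77L) {
  with_seed(seed, vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1)))
}

#' Spike organellar read pairs into a read set
#'
#' Adds pairs sampled from the organelle reference, at `fraction` of the
#' input pair count, with provenance `"organelle"`. The simulator
#' counterpart of the organelle-removal step in preprocessing.
#'
#' @param reads A [read_set()].
#' @param organelle Named character vector of organelle sequences (see
#'   [make_organelle_reference()]).
#' @param fraction Fraction (of the input pair count) of pairs to add, in
#'   `[0, 1)`.
#' @param insert_size,error_rate,quality Fragment model for the spiked pairs.
#' @param seed Integer seed.
#' @return A [read_set()] with the added pairs appended.
#' @export
spike_organelle <- function(reads, organelle, fraction,
                            insert_size = 500L, error_rate = 0.005,
                            quality = quality_model(), seed = 1L) {
  stopifnot(inherits(reads, "read_set"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_add <- round(fraction * n_pairs(reads))
  if (n_add == 0L) return(reads)
  L <- reads$read_length
  if (insert_size < 2L * L) stop("insert_size must be at least 2 * read_length")
  with_seed(seed, {
    src <- sample(seq_along(organelle), n_add, replace = TRUE,
                  prob = nchar(organelle))
    starts <- vapply(src, function(i) {
      sample.int(nchar(organelle[[i]]) - insert_size + 1L, 1L)
    }, integer(1))
    r1 <- substring(organelle[src], starts, starts + L - 1L)
    r2 <- revcomp_chr(substring(organelle[src],
                                starts + insert_size - L,
                                starts + insert_size - 1L))
    stems <- sprintf("%s_org%05d", reads$species_tag, seq_len(n_add))
    seq <- apply_errors(as.vector(rbind(r1, r2)), error_rate)
    names(seq) <- as.vector(rbind(paste0(stems, "/1"), paste0(stems, "/2")))
    qual <- stats::setNames(draw_qualities(2L * n_add, L, quality), names(seq))
    prov <- stats::setNames(rep("organelle", n_add), stems)
    read_set(c(reads$seq, seq), c(reads$qual, qual), reads$species_tag, L,
             provenance = c(reads$provenance, prov))
  })
}

#' Write a read set as FASTQ (Phred+33)
#' @param reads A [read_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file (Phred+33), read ids with /1 and /2 suffixes.
#' @param species_tag Four-letter code; defaults to the first four characters
#'   of the first read id.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, species_tag = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- sub(" .*", "", names(x))
  seq <- stats::setNames(as.character(x), ids)
  qual <- stats::setNames(as.character(S4Vectors::mcols(x)$qualities), ids)
  if (is.null(species_tag)) species_tag <- substr(ids[1], 1, 4)
  read_set(seq, qual, species_tag)
}

#' Write reads as interlaced FASTA
#'
#' Drops qualities and writes mates consecutively, the input format of the
#' clustering stage.
#' @inheritParams write_fastq
#' @return `path`, invisibly.
#' @export
write_interlaced_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Pool read sets from several species
#'
#' Concatenates read sets for comparative clustering. Species codes must be
#' distinct four-letter prefixes.
#' @param read_sets List of [read_set()] objects.
#' @return A pooled [read_set()] with `species_tag = NA`.
#' @export
pool_reads <- function(read_sets) {
  tags <- vapply(read_sets, `[[`, "", "species_tag")
  if (anyDuplicated(tags)) stop("duplicate species prefixes in pooled input")
  L <- unique(vapply(read_sets, `[[`, integer(1), "read_length"))
  if (length(L) != 1L) stop("read sets must share one read length")
  read_set(do.call(c, lapply(read_sets, `[[`, "seq")),
           do.call(c, lapply(read_sets, `[[`, "qual")),
           NA_character_, L,
           provenance = do.call(c, lapply(read_sets, `[[`, "provenance")))
}
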