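#' Similarity parameters for read clustering
#'
#' Defaults mirror the standard graph-based read-clustering settings: 90%
#' identity over at least 55% of the (shorter) read length, with clusters
#' reported only when they exceed 0.01% of the analyzed reads.
#'
#' @param min_identity Minimum alignment identity (matches / aligned
#'   columns); default 0.90.
#' @param min_overlap_fraction Minimum aligned span as a fraction of the
#'   shorter read; default 0.55.
#' @param kmer_seed_length Seed k-mer length for the candidate-pair
#'   prefilter; default 9. At the default identity/overlap thresholds the
#'   9-mer filter is provably lossless: a qualifying hit spans >= 55
#'   columns of which at most 10% mismatch, so >= 50 matching columns are
#'   broken into at most 6 runs and the longest exact run has >= 9
#'   columns — every true pair therefore shares a seed.
#' @param min_shared_kmers Candidate pairs must share at least this many
#'   canonical seed k-mers; default 1.
#' @param cluster_size_threshold Minimum cluster size as a fraction of the
#'   analyzed reads; default 1e-4 (0.01%). A floor of 2 reads always
#'   applies: a cluster is by definition a connected group.
#' @param min_pair_links Read pairs required to join two clusters into a
#'   supercluster; default 5.
#' @return A list with class `similarity_params`.
#' @export
similarity_params <- function(min_identity = 0.90,
                              min_overlap_fraction = 0.55,
                              kmer_seed_length = 9L,
                              min_shared_kmers = 1L,
                              cluster_size_threshold = 1e-4,
                              min_pair_links = 5L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_overlap_fraction > 0, min_overlap_fraction <= 1,
            cluster_size_threshold > 0, cluster_size_threshold <= 1,
            kmer_seed_length >= 5L, min_shared_kmers >= 1L)
  structure(list(min_identity = min_identity,
                 min_overlap_fraction = min_overlap_fraction,
                 kmer_seed_length = as.integer(kmer_seed_length),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 cluster_size_threshold = cluster_size_threshold,
                 min_pair_links = min_pair_links),
            class = "similarity_params")
}

# DNA scoring matrix: +1 match, -2 mismatch, N never matches anything.
# Mismatches are penalized harder than in unit scoring so that maximal local
# alignments do not drift through unrelated flanking sequence.
dna_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-2L, 5, 5, dimnames = list(b, b))
  diag(m) <- 1L
  m["N", "N"] <- -2L
  m
}

# Vectorized strand-fixed local alignment of many patterns against one
# subject. Returns identity (matches / aligned columns) and aligned columns.
align_local <- function(patterns, subject) {
  a <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns),
    Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = dna_submat(),
    gapOpening = 4, gapExtension = 2)
  cols <- Biostrings::nchar(a)
  list(identity = Biostrings::nmatch(a) / pmax(cols, 1L), cols = cols,
       score = Biostrings::score(a))
}

#' Pairwise read similarity
#'
#' Strand-aware best local alignment between two reads. A hit requires
#' identity of at least `min_identity` computed over the aligned columns,
#' and an aligned span of at least `min_overlap_fraction` of the shorter
#' read. Symmetric in its two arguments.
#'
#' @param a,b Read sequences (character).
#' @param params A [similarity_params()].
#' @return List with elements `hit` (logical), `identity`, `overlap`
#'   (aligned columns), `overlap_fraction` and `strand` (`"+"` or `"-"`).
#' @export
read_similarity <- function(a, b, params = similarity_params()) {
  min_len <- min(nchar(a), nchar(b))
  need <- span_needed(params$min_overlap_fraction, min_len)
  fw <- align_local(a, b)
  rv <- align_local(a, revcomp_chr(b))
  pick <- if (rv$score > fw$score) list(al = rv, strand = "-") else
    list(al = fw, strand = "+")
  # Prefer whichever strand yields a hit.
  hit_of <- function(al) al$identity >= params$min_identity & al$cols >= need
  if (!hit_of(pick$al)) {
    other <- if (pick$strand == "+") list(al = rv, strand = "-") else
      list(al = fw, strand = "+")
    if (hit_of(other$al)) pick <- other
  }
  list(hit = unname(hit_of(pick$al)),
       identity = unname(pick$al$identity),
       overlap = unname(pick$al$cols),
       overlap_fraction = unname(pick$al$cols / min_len),
       strand = pick$strand)
}

# Candidate read pairs sharing at least `min_shared` canonical k-mers.
# Returns a 2-column matrix of indices (i < j) into `seqs`. The canonical
# form of every distinct k-mer is computed once over a pooled dictionary.
candidate_pairs <- function(seqs, k = 9L, min_shared = 1L,
                            max_group = 2000L) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  kml <- lapply(seqs, function(s) {
    nn <- nchar(s)
    if (nn < k) return(character(0))
    km <- substring(s, seq_len(nn - k + 1L), k:nn)
    unique(km[!grepl("[^ACGT]", km)])
  })
  idx <- rep.int(seq_len(n), lengths(kml))
  all_km <- unlist(kml, use.names = FALSE)
  uk <- unique(all_km)
  canon <- stats::setNames(pmin(uk, revcomp_chr(uk)), uk)
  groups <- split(idx, canon[all_km])
  keys <- unlist(lapply(groups, function(v) {
    v <- unique(v)
    if (length(v) < 2L || length(v) > max_group) return(numeric(0))
    cb <- utils::combn(sort.int(v), 2L)
    (cb[1L, ] - 1) * n + cb[2L, ]
  }), use.names = FALSE)
  if (!length(keys)) return(matrix(integer(0), ncol = 2))
  tab <- table(keys)
  good <- as.numeric(names(tab)[tab >= min_shared])
  cbind(i = as.integer((good - 1) %/% n + 1), j = as.integer((good - 1) %% n + 1))
}
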