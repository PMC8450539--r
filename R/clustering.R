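#' Graph-based similarity clustering of reads
#'
#' Builds the read-similarity graph (vertices are reads; edges are
#' strand-aware local-alignment hits under `params`, with a shared-k-mer
#' prefilter to avoid all-vs-all alignment) and reports its connected
#' components as clusters. Components smaller than
#' `max(2, ceiling(cluster_size_threshold * analyzed reads))` are pooled
#' into the low/single-copy fraction. Reads are put in a canonical order
#' before component labelling, so the partition is invariant to input
#' order; cluster ids are assigned by decreasing size (ties broken by the
#' smallest member read id), `CL1` being the largest cluster.
#'
#' @param reads A [read_set()] (preprocessed; may be a [pool_reads()] pool).
#' @param params A [similarity_params()].
#' @param use_prefilter Use the k-mer candidate prefilter (default). Set to
#'   `FALSE` for brute-force all-pairs alignment; at the default identity
#'   threshold both give the same partition and the brute-force route
#'   serves as a small-input oracle.
#' @return An object of class `cluster_set`: `clusters` (data frame of id,
#'   size and per-species read counts), `membership` (named vector, read id
#'   to cluster id, `NA` for the low/single-copy pool), `degrees`,
#'   `analyzed` (per-species read totals), `species`, `params`, `reads`.
#' @export
build_cluster_graph <- function(reads, params = similarity_params(),
                                use_prefilter = TRUE) {
  stopifnot(inherits(reads, "read_set"))
  ids <- sort_c(names(reads$seq))
  seqs <- reads$seq[ids]
  n <- length(seqs)
  species <- sort_c(unique(substr(ids, 1, 4)))
  analyzed <- vapply(species, function(sp) {
    sum(substr(ids, 1, 4) == sp)
  }, integer(1))

  pairs <- if (use_prefilter) {
    candidate_pairs(seqs, k = params$kmer_seed_length,
                    min_shared = params$min_shared_kmers)
  } else {
    if (n >= 2L) {
      ap <- t(utils::combn(n, 2L))
      colnames(ap) <- c("i", "j")
      ap
    } else {
      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
    }
  }

  edge_i <- integer(0)
  edge_j <- integer(0)
  if (nrow(pairs) > 0L) {
    hit <- logical(nrow(pairs))
    min_len <- reads$read_length
    need <- span_needed(params$min_overlap_fraction, min_len)
    for (j in sort.int(unique(pairs[, "j"]))) {
      rows <- which(pairs[, "j"] == j)
      pat <- seqs[pairs[rows, "i"]]
      # both strands in one vectorized call
      a <- align_local(c(pat, revcomp_chr(pat)), seqs[[j]])
      m <- length(rows)
      pass <- a$identity >= params$min_identity & a$cols >= need
      hit[rows] <- pass[seq_len(m)] | pass[m + seq_len(m)]
    }
    edge_i <- pairs[hit, "i"]
    edge_j <- pairs[hit, "j"]
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(edge_i)) {
    g <- igraph::add_edges(g, rbind(ids[edge_i], ids[edge_j]))
  }
  comp <- igraph::components(g)
  degrees <- igraph::degree(g)

  min_size <- max(2L, ceiling(params$cluster_size_threshold * n))
  comp_sizes <- comp$csize[comp$membership]
  clustered <- comp_sizes >= min_size

  membership <- stats::setNames(rep(NA_character_, n), ids)
  cluster_rows <- NULL
  if (any(clustered)) {
    comps <- unique(comp$membership[clustered])
    first_id <- vapply(comps, function(cc) {
      min(ids[comp$membership == cc])
    }, character(1))
    sizes <- comp$csize[comps]
    ord <- order(-sizes, first_id)
    for (r in seq_along(ord)) {
      cc <- comps[ord[r]]
      membership[comp$membership == cc] <- sprintf("CL%d", r)
    }
    cm <- vapply(seq_along(ord), function(r) {
      inside <- ids[membership == sprintf("CL%d", r) & !is.na(membership)]
      vapply(species, function(sp) sum(substr(inside, 1, 4) == sp),
             integer(1))
    }, integer(length(species)))
    counts <- if (length(species) == 1L) matrix(cm, ncol = 1L) else t(cm)
    colnames(counts) <- paste0("reads_", species)
    cluster_rows <- data.frame(id = sprintf("CL%d", seq_along(ord)),
                               size = sizes[ord], counts,
                               stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    cluster_rows <- data.frame(id = character(0), size = integer(0))
  }

  structure(list(clusters = cluster_rows, membership = membership,
                 degrees = degrees, analyzed = analyzed, species = species,
                 min_cluster_size = min_size, params = params, reads = reads),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d reads (%s), %d clusters >= %d reads, %d in low/single-copy pool\n",
              length(x$membership),
              paste(sprintf("%s=%d", names(x$analyzed), x$analyzed),
                    collapse = ", "),
              nrow(x$clusters), x$min_cluster_size,
              sum(is.na(x$membership))))
  invisible(x)
}

#' Comparative clustering of several species' reads
#'
#' Runs the identical similarity clustering on the pooled read set of two or
#' more species, each down-sampled beforehand to the same genome proportion.
#' Reads keep their four-letter species prefixes, which provide the
#' per-cluster per-species counts; clusters with at least one read from each
#' species are shared clusters.
#'
#' @param read_sets List of per-species [read_set()] objects (distinct
#'   four-letter codes).
#' @param params A [similarity_params()].
#' @return A [build_cluster_graph()] result over the pooled reads.
#' @export
comparative_cluster <- function(read_sets, params = similarity_params()) {
  build_cluster_graph(pool_reads(read_sets), params = params)
}

#' Reads belonging to one cluster
#' @param cs A `cluster_set`.
#' @param id Cluster id, e.g. `"CL1"`.
#' @return Character vector of read ids.
#' @export
cluster_members <- function(cs, id) {
  names(cs$membership)[!is.na(cs$membership) & cs$membership == id]
}

#' Majority-vote consensus of a cluster
#'
#' Anchors the cluster on its most-connected read, overlays every member on
#' the anchor via its best strand-aware local alignment offset (the
#' simulator introduces substitutions only, so overlays are ungapped), and
#' takes the majority base per anchor position.
#'
#' @param cs A `cluster_set`.
#' @param id Cluster id.
#' @return Consensus sequence (character, anchor length).
#' @export
cluster_consensus <- function(cs, id) {
  members <- cluster_members(cs, id)
  stopifnot(length(members) >= 1L)
  seqs <- cs$reads$seq[members]
  anchor_id <- members[which.max(cs$degrees[members])]
  anchor <- cs$reads$seq[[anchor_id]]
  L <- nchar(anchor)
  votes <- matrix(0L, nrow = 4L, ncol = L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) {
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") s else revcomp_chr(s)
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(q), Biostrings::DNAString(anchor),
        type = "local", substitutionMatrix = dna_submat(),
        gapOpening = 4, gapExtension = 2)
      if (is.null(best) || Biostrings::score(a) > best$score) {
        best <- list(score = Biostrings::score(a), q = q,
                     offset = Biostrings::start(Biostrings::subject(a)) -
                       Biostrings::start(Biostrings::pattern(a)))
      }
    }
    ch <- strsplit(best$q, "", fixed = TRUE)[[1]]
    pos <- seq_along(ch) + best$offset
    keep <- pos >= 1L & pos <= L & ch %in% rownames(votes)
    for (kk in which(keep)) {
      votes[ch[kk], pos[kk]] <- votes[ch[kk], pos[kk]] + 1L
    }
  }
  paste(rownames(votes)[apply(votes, 2, which.max)], collapse = "")
}

#' Link clusters into superclusters via read pairs
#'
#' Two clusters are joined when at least `min_pairs` read pairs span them
#' (mate 1 in one cluster, mate 2 in the other). Superclusters are the
#' connected components of that cluster graph and partition the clusters;
#' with no spanning pairs (or an unreachable threshold) every cluster is
#' its own supercluster.
#'
#' @param cs A `cluster_set`.
#' @param min_pairs Minimum spanning pairs per link (default taken from the
#'   clustering parameters, 5).
#' @return Data frame with columns `cluster`, `supercluster`.
#' @export
link_superclusters <- function(cs, min_pairs = NULL) {
  min_pairs <- min_pairs %||% cs$params$min_pair_links
  cl_ids <- cs$clusters$id
  memb <- cs$membership
  stems <- unique(pair_stem(names(memb)))
  m1 <- memb[paste0(stems, "/1")]
  m2 <- memb[paste0(stems, "/2")]
  span <- !is.na(m1) & !is.na(m2) & m1 != m2
  edges <- NULL
  if (any(span)) {
    a <- pmin(m1[span], m2[span])
    b <- pmax(m1[span], m2[span])
    tab <- table(paste(a, b, sep = "\t"))
    good <- names(tab)[tab >= min_pairs]
    if (length(good)) {
      edges <- do.call(rbind, strsplit(good, "\t", fixed = TRUE))
    }
  }
  g <- igraph::make_empty_graph(n = length(cl_ids), directed = FALSE)
  igraph::V(g)$name <- cl_ids
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # Supercluster ids ordered by aggregate read count, largest first.
  agg <- tapply(cs$clusters$size, comp$membership[cl_ids], sum)
  first <- tapply(cl_ids, comp$membership[cl_ids], min)
  ord <- order(-agg, first)
  relabel <- stats::setNames(sprintf("SCL%d", seq_along(ord)),
                             names(agg)[ord])
  data.frame(cluster = cl_ids,
             supercluster = unname(relabel[as.character(comp$membership[cl_ids])]),
             stringsAsFactors = FALSE)
}

#' Write the cluster table as TSV
#'
#' One row per cluster: id, size, per-species read counts and genome
#' proportion (percent of that species' analyzed reads), plus annotation
#' and supercluster when supplied.
#'
#' @param cs A `cluster_set`.
#' @param path Output file.
#' @param annotation Optional [annotate_clusters()] result.
#' @param superclusters Optional [link_superclusters()] result.
#' @return The table, invisibly.
#' @export
write_cluster_table <- function(cs, path, annotation = NULL,
                                superclusters = NULL) {
  tab <- cs$clusters
  for (sp in cs$species) {
    tab[[paste0("gp_", sp)]] <-
      100 * tab[[paste0("reads_", sp)]] / cs$analyzed[[sp]]
  }
  if (!is.null(annotation)) {
    tab$annotation <- annotation$label[match(tab$id, annotation$id)]
  }
  if (!is.null(superclusters)) {
    tab$supercluster <-
      superclusters$supercluster[match(tab$id, superclusters$cluster)]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
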