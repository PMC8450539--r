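#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs ancestral values of a continuous trait (here, 1C genome
#' size in Mb) on a rooted tree with branch lengths. Under Brownian motion
#' the ML ancestral states (equivalently the GLS / best linear unbiased
#' estimates) minimize the branch-weighted sum of squared changes
#' `sum((x_parent - x_child)^2 / branch_length)`; they are obtained here by
#' solving the tree's weighted-Laplacian linear system with the tip values
#' fixed, which coincides with the re-rooting ("each node as the GLS root
#' of its re-rooted tree") formulation. The rate `sigma^2` is the ML
#' estimate (minimized quadratic form divided by the number of tips) and
#' node variances are the conditional-on-tips variances of the re-rooting
#' form, from which 95% intervals are reported. Estimates depend only on
#' relative branch lengths and are invariant to tip input order.
#'
#' Polytomies are resolved arbitrarily into zero-length-epsilon branches
#' (1e-8 of tree height) before solving; the ML solution is continuous in
#' branch lengths, so the estimates are unaffected to numerical precision.
#'
#' @param tree A rooted `phylo` tree with positive branch lengths.
#' @param tip_values Named numeric vector of trait values; names must match
#'   `tree$tip.label`.
#' @return Object of class `ancestral_bm`: `nodes` (data frame with `node`,
#'   `label`, `estimate`, `var`, `ci_lower`, `ci_upper`, `is_tip`),
#'   `sigma_squared`, and the (possibly dichotomized) `tree`.
#' @export
ml_ancestral_bm <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("need at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree)
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    tree$edge.length[tree$edge.length <= 0] <- eps
    message("polytomies resolved with epsilon-length branches")
  }
  if (any(tree$edge.length <= 0)) {
    stop("validation error: branch lengths must be positive")
  }
  missing <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing)) {
    stop("missing tip values for: ", paste(missing, collapse = ", "))
  }
  x_tip <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(x_tip)) stop("tip values must be numeric and complete")

  nnode <- tree$Nnode
  n_all <- ntip + nnode
  w <- 1 / tree$edge.length
  lap <- matrix(0, n_all, n_all)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    c_ <- tree$edge[e, 2L]
    lap[p, p] <- lap[p, p] + w[e]
    lap[c_, c_] <- lap[c_, c_] + w[e]
    lap[p, c_] <- lap[p, c_] - w[e]
    lap[c_, p] <- lap[c_, p] - w[e]
  }
  tips <- seq_len(ntip)
  internal <- (ntip + 1L):n_all
  luu_inv <- solve(lap[internal, internal, drop = FALSE])
  x_int <- as.numeric(luu_inv %*%
                        (-lap[internal, tips, drop = FALSE] %*% x_tip))
  x_all <- c(x_tip, x_int)

  ss <- sum(w * (x_all[tree$edge[, 1L]] - x_all[tree$edge[, 2L]])^2)
  sigma2 <- ss / ntip
  vars <- c(rep(0, ntip), sigma2 * diag(luu_inv))
  half <- stats::qnorm(0.975) * sqrt(vars)

  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) &&
                  length(tree$node.label) == nnode) tree$node.label
              else sprintf("node%d", internal))
  nodes <- data.frame(node = seq_len(n_all), label = labels,
                      estimate = x_all, var = vars,
                      ci_lower = x_all - half, ci_upper = x_all + half,
                      is_tip = seq_len(n_all) <= ntip,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, sigma_squared = sigma2, tree = tree),
            class = "ancestral_bm")
}

#' @export
print.ancestral_bm <- function(x, ...) {
  root <- ape::Ntip(x$tree) + 1L
  cat(sprintf("<ancestral_bm> %d tips; root estimate %.4g; sigma^2 = %.4g\n",
              ape::Ntip(x$tree), x$nodes$estimate[root], x$sigma_squared))
  invisible(x)
}

#' Per-tip genome-size change relative to a reference node
#'
#' Signed difference between each tip value and the reconstructed (or
#' supplied) value at a reference node: positive deltas are expansions,
#' negative deltas reductions.
#'
#' @param result An [ml_ancestral_bm()] result, or a named numeric vector
#'   of tip values.
#' @param reference For an `ancestral_bm` result: a node number or node
#'   label, or `"root"` (default). For a numeric vector of tip values: the
#'   reference value itself (e.g. an ancestral 1C in Mb).
#' @return Named numeric vector of per-tip deltas, in the units of the tip
#'   values.
#' @examples
#' branch_deltas(c(umbellata = 4680, koreana = 2480), 3022)
#' @export
branch_deltas <- function(result, reference = "root") {
  if (is.numeric(result)) {
    stopifnot(is.numeric(reference), length(reference) == 1L)
    return(result - reference)
  }
  stopifnot(inherits(result, "ancestral_bm"))
  nodes <- result$nodes
  ref_row <- if (identical(reference, "root")) {
    which(nodes$node == ape::Ntip(result$tree) + 1L)
  } else if (is.numeric(reference)) {
    which(nodes$node == reference)
  } else {
    which(nodes$label == reference)
  }
  if (length(ref_row) != 1L) stop("reference node not found")
  tips <- nodes[nodes$is_tip, ]
  stats::setNames(tips$estimate - nodes$estimate[ref_row], tips$label)
}

#' Simulate Brownian motion on a tree
#'
#' Draws one realization of a BM trait: starting from `root_value`, each
#' branch adds an independent normal increment with variance
#' `sigma_squared * branch length`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param root_value Trait value at the root.
#' @param sigma_squared BM rate (variance per unit branch length).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, root_value, sigma_squared, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), sigma_squared >= 0)
  ntip <- ape::Ntip(tree)
  with_seed(seed, {
    x <- numeric(ntip + tree$Nnode)
    x[ntip + 1L] <- root_value
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]
      c_ <- tr$edge[e, 2L]
      x[c_] <- x[p] + stats::rnorm(1, 0, sqrt(sigma_squared * tr$edge.length[e]))
    }
    stats::setNames(x[seq_len(ntip)], tree$tip.label)
  })
}

#' Read a tip-value table
#'
#' Two-column TSV (`label`, `value_mb`) mapping tip labels to 1C-values.
#' @param path TSV file.
#' @return Named numeric vector.
#' @export
read_tip_values <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(ncol(tab) >= 2L)
  stats::setNames(as.numeric(tab[[2L]]), tab[[1L]])
}
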