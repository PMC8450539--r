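# Independent oracles and small constructors used by several test files.

random_tree <- function(ntip, seed) {
  skimrep:::with_seed(seed, {
    tr <- ape::rtree(ntip)
    tr$edge.length <- tr$edge.length + 0.1
    tr
  })
}

# Numerically maximize the BM likelihood over ancestral states (minimize
# the branch-weighted sum of squared changes) — independent of the
# closed-form solver it checks.
optim_oracle <- function(tree, tip_values) {
  x_tip <- as.numeric(tip_values[tree$tip.label])
  objective <- function(x_int) {
    x <- c(x_tip, x_int)
    sum((x[tree$edge[, 1]] - x[tree$edge[, 2]])^2 / tree$edge.length)
  }
  start <- rep(mean(x_tip), tree$Nnode)
  fit <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit$par
}

toy_ltr_template <- function() {
  skimrep:::with_seed(3001, repeat_template(
    "ToyLTR", "Ty1/copia-Angela",
    ltr = paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = ""),
    internal = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                     collapse = "")))
}
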