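test_that("constant tip values reconstruct flat ancestors with zero rate", {
  tr <- random_tree(8, 201)
  vals <- stats::setNames(rep(3000, 8), tr$tip.label)
  res <- ml_ancestral_bm(tr, vals)
  expect_true(all(abs(res$nodes$estimate - 3000) < 1e-8))
  expect_equal(res$sigma_squared, 0, tolerance = 1e-12)
})

test_that("two equidistant tips average at the root", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  res <- ml_ancestral_bm(tr, c(a = 10, b = 20))
  expect_equal(res$nodes$estimate[res$nodes$node == 3], 15)
  # tip estimates equal observations
  expect_equal(res$nodes$estimate[1:2], c(10, 20))
  # unequal branches pull the root toward the closer tip
  tr2 <- ape::read.tree(text = "(a:1,b:3);")
  res2 <- ml_ancestral_bm(tr2, c(a = 10, b = 20))
  expect_equal(res2$nodes$estimate[3], 10 + (20 - 10) * (1 / 4), tolerance = 1e-9)
})

test_that("closed-form states match numerical likelihood maximization", {
  for (seed in c(211, 212, 213)) {
    tr <- random_tree(6, seed)
    vals <- stats::setNames(2500 + 200 * seq_len(6), tr$tip.label)
    res <- ml_ancestral_bm(tr, vals)
    internal <- res$nodes$estimate[!res$nodes$is_tip]
    oracle <- optim_oracle(tr, vals)
    expect_equal(internal, oracle, tolerance = 1e-6)
  }
})

test_that("estimates agree with the established phylogenetics packages", {
  tr <- random_tree(7, 221)
  vals <- skimrep:::with_seed(222,
    stats::setNames(3000 + cumsum(rnorm(7, 0, 200)), tr$tip.label))
  res <- ml_ancestral_bm(tr, vals)
  internal <- res$nodes$estimate[!res$nodes$is_tip]
  ace_fit <- ape::ace(vals[tr$tip.label], tr, method = "REML")
  # ace REML gives the same GLS states; compare states only
  expect_equal(unname(internal), unname(ace_fit$ace), tolerance = 1e-4)
  if (requireNamespace("phytools", quietly = TRUE)) {
    fa <- phytools::fastAnc(tr, vals[tr$tip.label])
    expect_equal(unname(internal), unname(as.numeric(fa)), tolerance = 1e-6)
  }
})

test_that("states are invariant under uniform branch rescaling", {
  tr <- random_tree(9, 231)
  vals <- stats::setNames(1000 + 100 * seq_len(9), tr$tip.label)
  res1 <- ml_ancestral_bm(tr, vals)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 7.5
  res2 <- ml_ancestral_bm(tr2, vals)
  expect_equal(res1$nodes$estimate, res2$nodes$estimate, tolerance = 1e-9)
  expect_equal(res1$sigma_squared / 7.5, res2$sigma_squared,
               tolerance = 1e-9)
})

test_that("degenerate trees are rejected with validation errors", {
  tr <- random_tree(4, 241)
  tr$edge.length[2] <- -0.5
  expect_error(ml_ancestral_bm(tr, stats::setNames(1:4, tr$tip.label)),
               "positive")
  tr2 <- random_tree(4, 242)
  expect_error(ml_ancestral_bm(tr2, stats::setNames(1:3, tr2$tip.label[1:3])),
               "missing tip values")
  one <- ape::read.tree(text = "(a:1);")
  expect_error(ml_ancestral_bm(one, c(a = 1)), "at least 2 tips")
})

test_that("polytomies are resolved without changing the estimates", {
  poly <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  vals <- c(a = 10, b = 20, c = 30, d = 40)
  res <- suppressMessages(ml_ancestral_bm(poly, vals))
  root_row <- which(!res$nodes$is_tip)[1]
  expect_equal(res$nodes$estimate[root_row], 25, tolerance = 1e-3)
})

test_that("branch deltas carry the documented sign convention", {
  deltas <- branch_deltas(c(umbellata = 4680, koreana = 2480), 3022)
  expect_equal(unname(deltas), c(1658, -542))
  expect_equal(branch_deltas(c(x = 5), 5), c(x = 0))
  tr <- ape::read.tree(text = "(a:1,b:1);")
  res <- ml_ancestral_bm(tr, c(a = 10, b = 20))
  d <- branch_deltas(res, "root")
  expect_equal(d, c(a = -5, b = 5))
})

test_that("tree-file and tip-table inputs reconstruct end to end", {
  tree <- ape::read.tree(system.file("extdata",
                                     "heloniadeae_toy_synthetic.nwk",
                                     package = "skimrep"))
  tips <- read_tip_values(system.file("extdata",
                                      "heloniadeae_toy_tip_values.tsv",
                                      package = "skimrep"))
  res <- ml_ancestral_bm(tree, tips)
  expect_equal(sum(res$nodes$is_tip), 8)
  root <- res$nodes$estimate[res$nodes$node == 9]
  expect_true(root > min(tips) && root < max(tips))
  d <- branch_deltas(res)
  expect_equal(unname(d["Heloniopsis_umbellata"] - d["Heloniopsis_koreana"]),
               4680 - 2480)
})

test_that("BM simulation plus reconstruction recovers the root on average", {
  tr <- random_tree(12, 251)
  root_true <- 3000
  sig2 <- 4e4
  roots <- vapply(1:60, function(r) {
    vals <- simulate_bm(tr, root_true, sig2, seed = 9000 + r)
    res <- ml_ancestral_bm(tr, vals)
    res$nodes$estimate[res$nodes$node == 13]
  }, numeric(1))
  se <- stats::sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - root_true), 2 * se + 1e-9)
})
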