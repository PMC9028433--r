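test_that("perfectly associated genes get the maximal rescaled weight", {
  set.seed(21)
  base <- rnorm(30)
  expr <- rbind(a = base, b = 2 * base + 5, c = rnorm(30))
  for (alg in c("clr", "aracne", "mrnet")) {
    net <- infer_adjacency(expr, alg, "spearman")
    expect_equal(net["a", "b"], 1)
  }
})

test_that("independent noise yields weak rescaled associations on average", {
  set.seed(22)
  expr <- matrix(rnorm(20 * 50), 20, 50,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  for (alg in c("clr", "aracne", "mrnet")) {
    net <- infer_adjacency(expr, alg, "pearson")
    expect_lt(mean(net[upper.tri(net)]), 0.25)
  }
})

test_that("ARACNE prunes the indirect edge of a chain (data-processing inequality)", {
  set.seed(23)
  x <- rnorm(300)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(300)
  z <- 0.9 * y + sqrt(1 - 0.81) * rnorm(300)
  expr <- rbind(x = x, y = y, z = z)
  # the DPI premise holds on the raw mutual information
  mi <- drugcombinet:::association_matrix(expr, "mi_empirical", "equal_freq")
  expect_lt(mi["x", "z"], min(mi["x", "y"], mi["y", "z"]))
  net <- infer_adjacency(expr, "aracne", "mi_empirical", "equal_freq")
  expect_equal(net["x", "z"], 0)
  expect_gt(net["x", "y"], 0)
  expect_gt(net["y", "z"], 0)
})

test_that("ARACNE output support is a subset of the raw association support", {
  set.seed(24)
  expr <- matrix(rnorm(15 * 40), 15, 40,
                 dimnames = list(sprintf("g%02d", 1:15), NULL))
  assoc <- drugcombinet:::association_matrix(expr, "pearson")
  net <- infer_adjacency(expr, "aracne", "pearson")
  expect_true(all(assoc[net > 0] > 0))
  pruned <- drugcombinet:::aracne_prune(assoc)
  expect_true(all(pruned <= assoc + 1e-12))
})

test_that("constant genes are zeroed with a warning", {
  set.seed(25)
  expr <- rbind(a = rnorm(20), b = rep(3, 20), c = rnorm(20))
  expect_warning(net <- infer_adjacency(expr, "clr", "pearson"), "constant")
  expect_equal(sum(net["b", ]), 0)
})

test_that("consensus of identical networks preserves edge ordering", {
  set.seed(26)
  m <- random_adjacency(6)
  cons <- consensus_network(list(m, m, m), n_keep = Inf)
  ut <- upper.tri(m)
  expect_equal(order(m[ut]), order(cons[ut]))
  # permutation invariance
  m2 <- random_adjacency(6); m3 <- random_adjacency(6)
  c1 <- consensus_network(list(m, m2, m3), n_keep = Inf)
  c2 <- consensus_network(list(m3, m, m2), n_keep = Inf)
  expect_identical(c1, c2)
  expect_error(consensus_network(list()), "empty")
})

test_that("consensus equals the hand-computed median of rank-normalized weights", {
  ids <- c("a", "b", "c")
  mk <- function(w) {
    m <- matrix(0, 3, 3, dimnames = list(ids, ids))
    m[upper.tri(m)] <- w
    m + t(m)
  }
  nets <- list(mk(c(0.9, 0.1, 0.5)), mk(c(0.2, 0.8, 0.4)), mk(c(0.7, 0.3, 0.6)))
  cons <- consensus_network(nets, n_keep = Inf)
  # per network: ranks of the three pair weights normalized to {0, 0.5, 1}
  norm <- sapply(nets, function(m) (rank(m[upper.tri(m)]) - 1) / 2)
  manual <- apply(norm, 1, median)
  expect_equal(cons[upper.tri(cons)], manual)
  # bounds and symmetry
  expect_true(all(cons >= 0 & cons <= 1))
  expect_identical(cons, t(cons))
})

test_that("consensus edge retention keeps exactly the strongest n_keep edges", {
  set.seed(27)
  nets <- replicate(3, random_adjacency(10, density = 1), simplify = FALSE)
  cons <- consensus_network(nets, n_keep = 12)
  expect_equal(sum(cons[upper.tri(cons)] > 0), 12)
  full <- consensus_network(nets, n_keep = Inf)
  kept <- cons[upper.tri(cons)]
  expect_true(min(full[upper.tri(full)][kept > 0]) >=
                max(full[upper.tri(full)][kept == 0]))
})

test_that("hub ranking puts a star center first and matches the Borda oracle", {
  ids <- c("hub", sprintf("leaf%d", 1:5))
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m["hub", ] <- m[, "hub"] <- 0.8
  diag(m) <- 0
  ss <- setNames(rep(1, 6), ids)
  rk <- rank_hub_genes(m, ss)
  expect_equal(rk$gene_id[rk$consensus_rank == 1], "hub")
  expect_setequal(rk$consensus_rank, 1:6)
})

test_that("Borda consensus equals brute-force mean-rank aggregation on random networks", {
  set.seed(28)
  for (trial in 1:5) {
    n <- sample(10:50, 1)
    m <- random_adjacency(n, density = 0.5)
    ss <- setNames(runif(n), rownames(m))
    rk <- rank_hub_genes(m, ss)
    # oracle: materialize the six ranked lists independently with igraph
    g <- igraph::graph_from_adjacency_matrix(m, "undirected", weighted = TRUE)
    w <- igraph::E(g)$weight
    dw <- 1 - w + 1e-6
    D <- igraph::distances(g, weights = dw); diag(D) <- NA
    msp <- apply(D, 1, function(r) { r <- r[is.finite(r)]
                                     if (!length(r)) Inf else mean(r) })
    cls <- suppressWarnings(igraph::closeness(g, weights = dw))
    cls[!is.finite(cls)] <- 0
    lists <- list(rank(-igraph::strength(g), ties.method = "average"),
                  rank(msp, ties.method = "average"),
                  rank(-igraph::betweenness(g, weights = dw), ties.method = "average"),
                  rank(-cls, ties.method = "average"),
                  rank(-igraph::eigen_centrality(g, weights = w)$vector,
                       ties.method = "average"),
                  rank(-ss, ties.method = "average"))
    lists <- lapply(lists, function(r) setNames(r, rownames(m)))
    oracle <- borda_oracle(lists, rownames(m))
    expect_equal(setNames(rk$consensus_rank, rk$gene_id)[names(oracle)], oracle)
  }
})

test_that("duplicating a rank list leaves mean-rank Borda order unchanged", {
  set.seed(29)
  ids <- letters[1:8]
  l1 <- setNames(sample(8), ids); l2 <- setNames(sample(8), ids)
  base <- borda_oracle(list(l1, l2), ids)
  dup <- borda_oracle(list(l1, l2, l2, l1), ids)
  expect_identical(base, dup)
})

test_that("ensemble consensus inference is deterministic and well-formed", {
  set.seed(30)
  expr <- matrix(rnorm(12 * 25), 12, 25,
                 dimnames = list(sprintf("g%02d", 1:12), NULL))
  n1 <- infer_consensus(expr)
  n2 <- infer_consensus(expr)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_identical(n1, t(n1))
  expect_equal(unname(diag(n1)), rep(0, 12))
  expect_silent(as_weighted_network(n1))
  expect_equal(nrow(ensemble_grid()), 12)
})

test_that("missing significance scores get the worst rank with a warning", {
  set.seed(31)
  m <- random_adjacency(5)
  ss <- setNames(runif(4), rownames(m)[1:4])
  expect_warning(rk <- rank_hub_genes(m, ss), "missing")
  expect_equal(rk$rank_ss[rk$gene_id == rownames(m)[5]], 5)
})
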