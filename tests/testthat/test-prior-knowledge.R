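mk_edges_layer <- function(cat, ...) {
  ed <- do.call(rbind, lapply(list(...), function(p) data.frame(a = p[1], b = p[2])))
  prior_layer(paste0(cat, "_x"), cat, ed, type = "edges")
}

test_that("bipartite projection connects genes sharing an association", {
  lay <- prior_layer("pw", "Functional",
                     data.frame(gene = c("A", "B"), term = c("P", "P")),
                     type = "bipartite")
  net <- project_layer(lay)
  expect_equal(net$edges, data.frame(gene_a = "A", gene_b = "B"))

  # no shared term, no edge
  lay2 <- prior_layer("pw", "Functional",
                      data.frame(gene = c("A", "B"), term = c("P1", "P2")),
                      type = "bipartite")
  expect_equal(nrow(project_layer(lay2)$edges), 0)

  # {P1: A,B,C} and {P2: C,D} -> exactly {AB, AC, BC, CD}
  lay3 <- prior_layer("pw", "Functional",
                      data.frame(gene = c("A", "B", "C", "C", "D"),
                                 term = c("P1", "P1", "P1", "P2", "P2")),
                      type = "bipartite")
  net3 <- project_layer(lay3)
  expect_equal(nrow(net3$edges), 4)
  expect_setequal(paste(net3$edges$gene_a, net3$edges$gene_b),
                  c("A B", "A C", "B C", "C D"))
})

test_that("bipartite projection equals brute-force pairwise term intersection", {
  set.seed(41)
  genes <- sprintf("g%d", 1:12); terms <- sprintf("t%d", 1:5)
  assoc <- unique(data.frame(gene = sample(genes, 40, TRUE),
                             term = sample(terms, 40, TRUE)))
  net <- project_layer(prior_layer("r", "Functional", assoc, "bipartite"))
  keys <- character()
  for (i in seq_along(genes)) for (j in seq_len(i - 1)) {
    ti <- assoc$term[assoc$gene == genes[i]]
    tj <- assoc$term[assoc$gene == genes[j]]
    if (length(intersect(ti, tj))) keys <- c(keys, paste(sort(c(genes[i], genes[j])), collapse = "|"))
  }
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b, sep = "|"), keys)
})

test_that("gene-gene layers pass through symmetrized and deduplicated", {
  lay <- prior_layer("ppi", "Interaction",
                     data.frame(a = c("A", "B", "A", "C"),
                                b = c("B", "A", "B", "C")), "edges")
  net <- project_layer(lay)
  expect_equal(net$edges, data.frame(gene_a = "A", gene_b = "B"))
  expect_warning(empty <- project_layer(
    prior_layer("e", "Regulation", data.frame(a = character(), b = character()),
                "edges")), "empty")
  expect_equal(nrow(empty$edges), 0)
})

test_that("category merge is an edge-set union with set semantics", {
  n1 <- binary_network(data.frame(a = "A", b = "B"))
  n2 <- binary_network(data.frame(a = c("B", "A"), b = c("C", "B")))
  merged <- merge_category(list(n1, n2))
  expect_setequal(paste(merged$edges$gene_a, merged$edges$gene_b),
                  c("A B", "B C"))
  # inclusion-exclusion on random layers
  set.seed(42)
  for (i in 1:10) {
    e1 <- unique(data.frame(a = sample(LETTERS[1:8], 12, TRUE),
                            b = sample(LETTERS[1:8], 12, TRUE)))
    e2 <- unique(data.frame(a = sample(LETTERS[1:8], 12, TRUE),
                            b = sample(LETTERS[1:8], 12, TRUE)))
    b1 <- binary_network(e1); b2 <- binary_network(e2)
    k1 <- paste(b1$edges$gene_a, b1$edges$gene_b)
    k2 <- paste(b2$edges$gene_a, b2$edges$gene_b)
    m <- merge_category(list(b1, b2))
    expect_equal(nrow(m$edges),
                 length(k1) + length(k2) - length(intersect(k1, k2)))
  }
  # associativity / order independence
  n3 <- binary_network(data.frame(a = "C", b = "D"))
  expect_identical(merge_category(list(n1, n2, n3))$edges,
                   merge_category(list(n3, merge_category(list(n2, n1))))$edges)
})

test_that("category intersection keeps only triple-supported edges", {
  i1 <- binary_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  r1 <- binary_network(data.frame(a = c("A", "E"), b = c("B", "F")))
  f1 <- binary_network(data.frame(a = c("B", "C"), b = c("A", "D")))
  out <- intersect_categories(i1, r1, f1)
  expect_equal(out$edges, data.frame(gene_a = "A", gene_b = "B"))
  expect_warning(intersect_categories(i1, binary_network(), f1), "EMPTY")

  # random instance vs brute-force triple intersection
  set.seed(43)
  rnd <- function() binary_network(data.frame(a = sample(LETTERS[1:6], 10, TRUE),
                                              b = sample(LETTERS[1:6], 10, TRUE)))
  for (i in 1:10) {
    a <- rnd(); b <- rnd(); c <- rnd()
    got <- suppressWarnings(intersect_categories(a, b, c))
    ka <- paste(a$edges$gene_a, a$edges$gene_b)
    kb <- paste(b$edges$gene_a, b$edges$gene_b)
    kc <- paste(c$edges$gene_a, c$edges$gene_b)
    expect_setequal(paste(got$edges$gene_a, got$edges$gene_b),
                    intersect(intersect(ka, kb), kc))
  }
})

test_that("prior filtering keeps supported edges, weights and isolated nodes", {
  set.seed(44)
  coexpr <- random_adjacency(8, density = 0.6)
  ed <- adjacency_to_edges(coexpr)
  # prior covering everything: identity
  prior_all <- binary_network(ed[, 1:2])
  expect_equal(filter_disease_network(coexpr, prior_all), coexpr)
  # empty prior: edgeless, node set retained
  expect_warning(f0 <- filter_disease_network(coexpr, binary_network()), "supported")
  expect_equal(sum(f0), 0)
  expect_identical(rownames(f0), rownames(coexpr))
  # random prior equals brute-force membership test
  keep <- ed[sample(nrow(ed), 4), 1:2]
  prior <- binary_network(keep)
  filt <- suppressWarnings(filter_disease_network(coexpr, prior))
  for (r in seq_len(nrow(ed))) {
    expected <- if (paste(ed$gene_a[r], ed$gene_b[r]) %in% paste(keep$gene_a, keep$gene_b))
      ed$weight[r] else 0
    expect_equal(filt[ed$gene_a[r], ed$gene_b[r]], expected)
  }
})

test_that("prior construction is monotone in layers and edges", {
  set.seed(45)
  lay1 <- mk_edges_layer("Interaction", c("A", "B"), c("C", "D"))
  lay2 <- mk_edges_layer("Interaction", c("E", "F"))
  m1 <- merge_category(lapply(list(lay1), project_layer))
  m2 <- merge_category(lapply(list(lay1, lay2), project_layer))
  expect_true(all(paste(m1$edges$gene_a, m1$edges$gene_b) %in%
                    paste(m2$edges$gene_a, m2$edges$gene_b)))

  layers <- list(mk_edges_layer("Interaction", c("A", "B")),
                 mk_edges_layer("Regulation", c("A", "B")),
                 mk_edges_layer("Functional", c("A", "B")))
  p1 <- build_prior_network(layers)
  layers2 <- lapply(layers, function(l) {
    l$associations <- rbind(l$associations, data.frame(a = "C", b = "D"))
    l
  })
  p2 <- build_prior_network(layers2)
  expect_true(all(paste(p1$edges$gene_a, p1$edges$gene_b) %in%
                    paste(p2$edges$gene_a, p2$edges$gene_b)))
  expect_error(build_prior_network(layers[1:2]), "no layer")
})
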