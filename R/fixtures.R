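#' Simulate paired disease/control expression with planted signal
#'
#' Generates an FPKM-like paired cohort on the log-normal scale with
#' block-correlated gene modules and two planted gene classes:
#'
#' * *differential-mean* genes get a log2 mean shift (`effect_sizes$mean_shift`,
#'   random sign) in disease samples at unchanged variance;
#' * *differential-variance* genes get their disease-sample residual
#'   variance inflated by `effect_sizes$var_factor` plus a half-size mean
#'   shift (so that the significance score, which multiplies by the fold
#'   change, can rank them).
#'
#' Pairing is induced by a per-subject random effect shared between the two
#' conditions.  Planted genes fill the leading modules so that the selected
#' candidate set retains module structure.
#'
#' @param G gene count.
#' @param pairs matched subject pairs (the pipeline's input gate asks for at
#'   least 10).
#' @param n_modules number of equally sized correlated modules.
#' @param de_frac,var_frac fractions of genes planted as differential-mean /
#'   differential-variance (disjoint sets).
#' @param effect_sizes list with `mean_shift` (log2 units) and `var_factor`
#'   (disease/control variance ratio).
#' @param module_cor within-module correlation of the log-scale residuals.
#' @param seed RNG seed.
#' @return list with `expr` (an [expression_set()]) and `truth` (list:
#'   `planted_de_genes`, `planted_var_genes`, `module_assignment`,
#'   `truth_network` — a [binary_network()] of within-module pairs).
#' @export
simulate_disease_expression <- function(G = 300L, pairs = 20L,
                                        n_modules = 10L,
                                        de_frac = 0.10, var_frac = 0.10,
                                        effect_sizes = list(mean_shift = 1.5,
                                                            var_factor = 4),
                                        module_cor = 0.6, seed = 1L) {
  if (de_frac + var_frac > 1) stop2("de_frac + var_frac must be <= 1")
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(G))
  module <- sort(rep(seq_len(n_modules), length.out = G))
  names(module) <- genes
  n_de <- floor(de_frac * G)
  n_var <- floor(var_frac * G)
  de_genes <- genes[seq_len(n_de)]
  var_genes <- genes[n_de + seq_len(n_var)]

  subjects <- sprintf("S%02d", seq_len(pairs))
  sample_ids <- c(paste0(subjects, "_d"), paste0(subjects, "_c"))
  n_samp <- 2L * pairs
  is_disease <- rep(c(TRUE, FALSE), each = pairs)

  mu <- rnorm(G, 6, 1.5)
  u <- rnorm(pairs, 0, 0.7)
  fac <- matrix(rnorm(n_modules * n_samp), n_modules, n_samp)
  eps <- matrix(rnorm(G * n_samp), G, n_samp)
  y <- matrix(mu, G, n_samp) +
    matrix(rep(u, 2), G, n_samp, byrow = TRUE) +
    sqrt(module_cor) * fac[module, ] +
    sqrt(1 - module_cor) * eps

  shift <- numeric(G); names(shift) <- genes
  shift[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) * effect_sizes$mean_shift
  shift[var_genes] <- sample(c(-1, 1), n_var, replace = TRUE) *
    effect_sizes$mean_shift / 2
  y[, is_disease] <- y[, is_disease] + shift

  # variance inflation of the whole residual (module + noise) in disease
  resid <- sqrt(module_cor) * fac[module, is_disease, drop = FALSE] +
    sqrt(1 - module_cor) * eps[, is_disease, drop = FALSE]
  infl <- (sqrt(effect_sizes$var_factor) - 1) * resid[genes %in% var_genes, , drop = FALSE]
  y[genes %in% var_genes, is_disease] <- y[genes %in% var_genes, is_disease] + infl

  values <- 2^y
  rownames(values) <- genes
  colnames(values) <- sample_ids
  meta <- data.frame(sample_id = sample_ids,
                     subject_id = rep(subjects, 2),
                     condition = ifelse(is_disease, "disease", "control"),
                     stringsAsFactors = FALSE)
  expr <- expression_set(values, meta, min_pairs = 2L)

  edge_rows <- lapply(seq_len(n_modules), function(m) {
    g <- genes[module == m]
    if (length(g) < 2L) return(NULL)
    cmb <- utils::combn(g, 2L)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
  })
  truth_net <- binary_network(do.call(rbind, edge_rows), nodes = genes)

  list(expr = expr,
       truth = list(planted_de_genes = de_genes,
                    planted_var_genes = var_genes,
                    module_assignment = module,
                    truth_network = truth_net))
}

#' Simulate noisy prior-knowledge layers from a ground-truth network
#'
#' Produces `n_per_category` gene-gene layers for each of the three
#' categories (Interaction, Regulation, Functional; 3 x 3 = 9 layers at the
#' default, mirroring a realistically sized source collection).  Every
#' truth edge is assigned to at least one layer of every category, so at
#' `edge_noise = 0` and full subsampling the triple intersection recovers
#' the truth network exactly; spurious (non-truth) edges are added to each
#' layer at rate `edge_noise` and survive the final intersection only if
#' they are generated independently in all three categories.
#'
#' @param truth a [binary_network()] of true associations.
#' @param n_per_category layers per category (>= 1).
#' @param edge_noise spurious edges per layer as a fraction of truth edges.
#' @param subsample probability that a truth edge is additionally present
#'   in any given layer (beyond its guaranteed one per category).
#' @param seed RNG seed.
#' @return list of [prior_layer()] objects.
#' @export
simulate_prior_layers <- function(truth, n_per_category = 3L,
                                  edge_noise = 0.05, subsample = 0.7,
                                  seed = 1L) {
  if (n_per_category < 1L) stop2("n_per_category must be >= 1")
  set.seed(seed)
  ed <- truth$edges
  ne <- nrow(ed)
  nodes <- truth$nodes
  truth_keys <- edge_keys(truth)
  layers <- list()
  for (cat in c("Interaction", "Regulation", "Functional")) {
    anchor <- sample.int(n_per_category, ne, replace = TRUE)
    for (l in seq_len(n_per_category)) {
      keep <- anchor == l | runif(ne) < subsample
      lay <- ed[keep, , drop = FALSE]
      n_spur <- round(edge_noise * ne)
      if (n_spur > 0L) {
        a <- sample(nodes, 4L * n_spur, replace = TRUE)
        b <- sample(nodes, 4L * n_spur, replace = TRUE)
        ok <- a != b & !(edge_key(a, b) %in% truth_keys)
        spur <- unique(data.frame(gene_a = pmin(a[ok], b[ok]),
                                  gene_b = pmax(a[ok], b[ok]),
                                  stringsAsFactors = FALSE))
        spur <- head(spur, n_spur)
        lay <- rbind(lay, spur)
      }
      layers[[length(layers) + 1L]] <-
        prior_layer(sprintf("%s_%d", tolower(cat), l), cat, lay, type = "edges")
    }
  }
  layers
}

#' Simulate a drug library with a planted ideal combination
#'
#' Generates `K` drugs against a disease network:
#'
#' * the two *planted* drugs target the most central genes of the two
#'   largest connected components (disjoint, far-apart target sets with top
#'   ranks, hence maximal target dispersion and effect score);
#' * the remaining drugs draw a few targets from the less central half of a
#'   single component (functionally redundant);
#' * each drug gets `n_replicates` perturbational replicate profiles over a
#'   landmark gene panel; the planted pair perturbs complementary halves of
#'   the panel's modules (maximally dissimilar mechanism of action) while
#'   the others perturb overlapping random module subsets;
#' * SMILES-like strings come from a small token grammar; the planted pair
#'   uses disjoint alphabets and very different lengths (maximal edit
#'   distance).  No chemical validity is attempted — only the string-distance
#'   structure matters to the method.
#'
#' @param K drug count (>= 4).
#' @param disease_net weighted adjacency matrix of the (filtered) disease
#'   network.
#' @param landmark_genes size of the landmark panel for MOA profiles.
#' @param n_replicates replicates per drug (> 5 so all drugs pass the MOA
#'   filter).
#' @param ranking optional `node_ranking` over `disease_net` used to pick
#'   central targets; defaults to a strength-based ranking.
#' @param seed RNG seed.
#' @return list with `drugs` (list of [drug_record()]) and `truth` (list
#'   with `planted_combination` and per-drug `perturbed_modules`).
#' @export
simulate_drug_library <- function(K = 20L, disease_net, landmark_genes = 100L,
                                  n_replicates = 8L, ranking = NULL,
                                  seed = 1L) {
  if (K < 4L) stop2("K must be >= 4")
  set.seed(seed)
  nodes <- rownames(disease_net)
  g <- weighted_to_igraph(disease_net)
  comp <- igraph::components(g)
  ord_comp <- order(-comp$csize)
  if (sum(comp$csize >= 2L) < 2L) {
    stop2("disease network too small for the requested target dispersion: ",
          "need two components with >= 2 nodes")
  }
  big <- ord_comp[1:2]
  # planted drugs target the hubs of the two largest components; cap by the
  # smaller of the two so both planted target sets are equally sized
  n_target_planted <- max(2L, min(8L, floor(comp$csize[big[2]] / 2)))
  if (is.null(ranking)) {
    s <- igraph::strength(g)
    ranking <- data.frame(gene_id = nodes,
                          consensus_rank = rank_desc_lex(s, nodes),
                          stringsAsFactors = FALSE)
  }
  rk <- setNames(ranking$consensus_rank, ranking$gene_id)[nodes]
  members <- lapply(big, function(ci) nodes[comp$membership == ci])
  top_of <- function(gs, k) gs[order(rk[gs])][seq_len(k)]
  # peripheral target pool: worst-ranked half *within* a component, so the
  # redundant drugs stay clearly less central than the planted hubs even
  # when one component outranks the other globally
  worst_of <- function(gs) gs[order(rk[gs])][-seq_len(ceiling(length(gs) / 2))]

  drug_ids <- sprintf("drug%02d", seq_len(K))
  planted <- drug_ids[1:2]
  targets <- vector("list", K); names(targets) <- drug_ids
  targets[[1]] <- top_of(members[[1]], n_target_planted)
  targets[[2]] <- top_of(members[[2]], n_target_planted)
  for (i in 3:K) {
    home <- members[[1 + (i %% 2L)]]
    pool <- setdiff(worst_of(home), c(targets[[1]], targets[[2]]))
    if (length(pool) < 1L) pool <- setdiff(home, c(targets[[1]], targets[[2]]))
    targets[[i]] <- sample(pool, min(3L, length(pool)))
  }

  # landmark panel with 10 modules; every drug perturbs exactly five of
  # them, so all MOA networks share one global structure and pairwise HIM
  # is governed by module overlap: the planted pair perturbs complementary
  # (disjoint) halves, every other pair overlaps in at least one module
  panel <- sprintf("L%03d", seq_len(landmark_genes))
  n_lm_mod <- 10L
  lm_module <- sort(rep(seq_len(n_lm_mod), length.out = landmark_genes))
  perturbed <- vector("list", K); names(perturbed) <- drug_ids
  perturbed[[1]] <- 1:5
  perturbed[[2]] <- 6:10
  for (i in 3:K) perturbed[[i]] <- sort(sample(2:9, 5L))

  profiles <- lapply(seq_len(K), function(i) {
    fac <- matrix(rnorm(n_lm_mod * n_replicates), n_lm_mod, n_replicates)
    noise <- matrix(rnorm(landmark_genes * n_replicates), landmark_genes)
    load <- ifelse(lm_module %in% perturbed[[i]], 3, 0)
    x <- load * fac[lm_module, ] + noise
    rownames(x) <- panel
    colnames(x) <- sprintf("rep%02d", seq_len(n_replicates))
    x
  })

  tok_common <- c("C", "c", "N", "O", "(", ")", "=", "1", "2", "S", "l")
  tok_alt <- c("P", "I", "B", "r", "[", "]", "@", "+", "5", "6", "F")
  smiles <- character(K)
  smiles[1] <- paste(sample(tok_common, 8L, replace = TRUE), collapse = "")
  smiles[2] <- paste(sample(tok_alt, 40L, replace = TRUE), collapse = "")
  for (i in 3:K) {
    smiles[i] <- paste(sample(tok_common, sample(14:22, 1L), replace = TRUE),
                       collapse = "")
  }

  drugs <- lapply(seq_len(K), function(i) {
    drug_record(drug_ids[i], smiles[i], targets[[i]], profiles[[i]])
  })
  list(drugs = drugs,
       truth = list(planted_combination = planted,
                    perturbed_modules = perturbed,
                    landmark_module = setNames(lm_module, panel)))
}

#' Build the package's default synthetic study end to end
#'
#' Runs the full disease side of the pipeline on the default fixture
#' (300 genes, 20 matched pairs, 10 modules) — candidate-gene scoring,
#' ensemble consensus co-expression on the selected genes, prior
#' construction and filtering, Borda hub ranking — then simulates the
#' 20-drug library with its planted ideal pair against the resulting
#' network and computes the drug feature tables.
#'
#' @param seed RNG seed driving every stage.
#' @param K drugs in the library.
#' @param landmark_genes landmark panel size for MOA profiles.
#' @param ... overrides passed to [simulate_disease_expression()].
#' @return list with elements `expr`, `truth`, `scores`, `selected`,
#'   `coexpr`, `prior`, `network` (filtered), `ranking`, `library`,
#'   `feats`.
#' @export
build_default_fixture <- function(seed = 1L, K = 20L, landmark_genes = 100L,
                                  ...) {
  sim <- simulate_disease_expression(seed = seed, ...)
  scores <- suppressWarnings(score_genes(sim$expr))
  selected <- select_candidate_genes(scores)
  sub <- log2(sim$expr$values[selected, , drop = FALSE] + 1)
  coexpr <- suppressWarnings(infer_consensus(sub))
  layers <- simulate_prior_layers(sim$truth$truth_network, seed = seed + 1L)
  prior <- build_prior_network(layers)
  filtered <- filter_disease_network(coexpr, prior)
  ss <- setNames(pmax(scores$SS_wilcoxon, scores$SS_ftest), scores$gene_id)
  ranking <- rank_hub_genes(filtered, ss)
  lib <- simulate_drug_library(K = K, disease_net = filtered,
                               landmark_genes = landmark_genes,
                               ranking = ranking, seed = seed + 2L)
  feats <- build_feature_tables(lib$drugs, filtered, ranking)
  list(expr = sim$expr, truth = c(sim$truth, lib$truth),
       scores = scores, selected = selected, coexpr = coexpr,
       prior = prior, network = filtered, ranking = ranking,
       library = lib$drugs, feats = feats)
}
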