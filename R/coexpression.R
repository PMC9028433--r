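#' Gene co-expression network inference (ensemble)
#'
#' Pairwise association scores (absolute Pearson/Spearman correlation or
#' empirical mutual information on discretized data) are post-processed by
#' one of three classic inference algorithms:
#'
#' * **CLR**: each raw score is replaced by the z-score against its row and
#'   column background, `sqrt(max(0, z_i)^2 + max(0, z_j)^2)`;
#' * **ARACNE**: data-processing-inequality pruning — in every triangle the
#'   strictly weakest edge (within tolerance `eps`) is removed;
#' * **MRNET**: max-relevance-min-redundancy forward-selection scores,
#'   symmetrized by the maximum.
#'
#' The post-processed matrix is min-max rescaled to `[0, 1]`.
#'
#' @param expr numeric matrix, genes x samples.
#' @param algorithm one of `"clr"`, `"aracne"`, `"mrnet"`.
#' @param estimator one of `"pearson"`, `"spearman"`, `"mi_empirical"`.
#' @param discretizer for `mi_empirical` only: `"equal_freq"` (quantile
#'   bins) or `"equal_width"`.
#' @param bins number of bins for discretization; default
#'   `max(2, floor(sqrt(n_samples)))`.
#' @param eps ARACNE DPI tolerance (default 0: strictly weakest edge of each
#'   triangle is pruned).
#' @return weighted adjacency matrix (see [as_weighted_network()]).
#' @export
infer_adjacency <- function(expr,
                            algorithm = c("clr", "aracne", "mrnet"),
                            estimator = c("pearson", "spearman", "mi_empirical"),
                            discretizer = c("equal_freq", "equal_width"),
                            bins = NULL, eps = 0) {
  algorithm <- match.arg(algorithm)
  estimator <- match.arg(estimator)
  discretizer <- match.arg(discretizer)
  if (!is.matrix(expr) || nrow(expr) < 2L) stop2("need a matrix with >= 2 genes")
  if (ncol(expr) < 3L) stop2("need >= 3 samples")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))

  assoc <- association_matrix(expr, estimator, discretizer, bins)
  apply_inference <- switch(algorithm,
    clr = clr_transform,
    aracne = function(a) aracne_prune(a, eps = eps),
    mrnet = mrnet_scores
  )
  out <- apply_inference(assoc)
  diag(out) <- 0
  out <- (out + t(out)) / 2
  rescale_minmax(out)
}

# raw pairwise association matrix for one estimator/discretizer setting
association_matrix <- function(expr, estimator, discretizer = "equal_freq",
                               bins = NULL) {
  const <- apply(expr, 1, function(x) max(x) == min(x))
  if (any(const)) {
    warning(sum(const), " constant gene(s): associations set to 0", call. = FALSE)
  }
  assoc <- switch(estimator,
    pearson = abs(suppressWarnings(cor(t(expr), method = "pearson"))),
    spearman = abs(suppressWarnings(cor(t(expr), method = "spearman"))),
    mi_empirical = mi_matrix(expr, discretizer, bins)
  )
  assoc[!is.finite(assoc)] <- 0
  assoc[const, ] <- 0
  assoc[, const] <- 0
  diag(assoc) <- 0
  (assoc + t(assoc)) / 2
}

# empirical mutual information (nats) on discretized rows
mi_matrix <- function(expr, discretizer, bins = NULL) {
  n <- ncol(expr)
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  disc <- t(apply(expr, 1, discretize_vec, bins = bins, method = discretizer))
  g <- nrow(expr)
  nb <- max(disc)
  # per-gene marginal entropies, then pairwise joint entropies via
  # integer-coded tabulation (much faster than per-pair contingency tables)
  hx <- apply(disc, 1, function(x) {
    p <- tabulate(x, nb) / n
    -sum(p[p > 0] * log(p[p > 0]))
  })
  mim <- matrix(0, g, g, dimnames = list(rownames(expr), rownames(expr)))
  for (i in seq_len(g - 1L)) {
    code_i <- (disc[i, ] - 1L) * nb
    for (j in (i + 1L):g) {
      p <- tabulate(code_i + disc[j, ], nb * nb) / n
      hxy <- -sum(p[p > 0] * log(p[p > 0]))
      mim[i, j] <- mim[j, i] <- max(hx[i] + hx[j] - hxy, 0)
    }
  }
  mim
}

discretize_vec <- function(x, bins, method) {
  if (max(x) == min(x)) return(rep(1L, length(x)))
  br <- if (method == "equal_width") {
    seq(min(x), max(x), length.out = bins + 1L)
  } else {
    unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L), type = 7))
  }
  if (length(br) < 2L) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

clr_transform <- function(assoc) {
  mu <- rowMeans(assoc)
  sdv <- apply(assoc, 1, sd)
  z <- (assoc - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z <- pmax(z, 0)
  sqrt(z^2 + t(z)^2)
}

aracne_prune <- function(assoc, eps = 0) {
  n <- nrow(assoc)
  maxmin <- matrix(0, n, n)
  for (k in seq_len(n)) {
    v <- assoc[, k]
    maxmin <- pmax(maxmin, pmin(matrix(v, n, n), matrix(v, n, n, byrow = TRUE)))
  }
  out <- assoc
  out[assoc < maxmin - eps] <- 0
  out
}

mrnet_scores <- function(assoc) {
  n <- nrow(assoc)
  scores <- matrix(0, n, n, dimnames = dimnames(assoc))
  for (t in seq_len(n)) {
    rel <- assoc[t, ]
    rel[t] <- -Inf
    open <- rep(TRUE, n); open[t] <- FALSE
    redsum <- numeric(n)
    nsel <- 0L
    s <- numeric(n)
    while (any(open)) {
      cand <- if (nsel == 0L) rel else rel - redsum / nsel
      cand[!open] <- -Inf
      best <- which.max(cand)
      if (cand[best] <= 0) break  # weaker predictors keep score 0
      s[best] <- cand[best]
      redsum <- redsum + assoc[, best]
      nsel <- nsel + 1L
      open[best] <- FALSE
    }
    scores[t, ] <- s
  }
  pmax(pmax(scores, t(scores)), 0)
}

rescale_minmax <- function(mat) {
  off <- mat[upper.tri(mat)]
  lo <- min(off); hi <- max(off)
  if (hi == lo) {
    mat[] <- 0
  } else {
    mat <- (mat - lo) / (hi - lo)
    mat[mat < 0] <- 0
  }
  diag(mat) <- 0
  mat
}

#' Default inference ensemble grid
#'
#' All combinations of `{clr, aracne, mrnet}` with `{pearson, spearman,
#' mi_empirical}`; the two discretizers apply to the mutual-information
#' estimator only, giving 12 member networks.
#'
#' @param algorithms,estimators,discretizers character subsets of the grid.
#' @return data frame with columns `algorithm`, `estimator`, `discretizer`
#'   (`NA` for correlation estimators).
#' @export
ensemble_grid <- function(algorithms = c("clr", "aracne", "mrnet"),
                          estimators = c("pearson", "spearman", "mi_empirical"),
                          discretizers = c("equal_freq", "equal_width")) {
  rows <- list()
  for (alg in algorithms) for (est in estimators) {
    if (est == "mi_empirical") {
      for (d in discretizers) rows[[length(rows) + 1L]] <- c(alg, est, d)
    } else {
      rows[[length(rows) + 1L]] <- c(alg, est, NA_character_)
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("algorithm", "estimator", "discretizer")
  out
}

#' Consensus of an ensemble of weighted networks
#'
#' Each member adjacency is edge-rank-normalized to `[0, 1]` (average ranks
#' over all unordered pairs, scaled so the weakest pair maps to 0 and the
#' strongest to 1); the consensus weight of a pair is the element-wise
#' median of the normalized ranks.  Only the strongest `n_keep` edges are
#' retained (default `2 * N`); ties at the cutoff are broken by gene-pair
#' order for determinism.
#'
#' @param networks list of adjacency matrices over the same node set.
#' @param n_keep number of edges kept (use `Inf` to keep all).
#' @return consensus weighted adjacency matrix.
#' @export
consensus_network <- function(networks, n_keep = NULL) {
  if (length(networks) == 0L) stop2("empty network list")
  ids <- rownames(networks[[1]])
  for (m in networks) {
    if (!identical(rownames(m), ids)) stop2("all networks must share one node set")
  }
  n <- length(ids)
  if (is.null(n_keep)) n_keep <- 2L * n
  ut <- upper.tri(networks[[1]])
  e <- sum(ut)
  norm_ranks <- vapply(networks, function(m) {
    r <- rank(m[ut], ties.method = "average")
    if (e > 1L) (r - 1) / (e - 1) else rep(1, e)
  }, numeric(e))
  cons <- apply(norm_ranks, 1, median)
  if (is.finite(n_keep) && n_keep < e) {
    idx <- which(ut, arr.ind = TRUE)
    ord <- order(-cons, ids[idx[, 1]], ids[idx[, 2]], method = "radix")
    drop <- ord[-seq_len(n_keep)]
    cons[drop] <- 0
  }
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  out[ut] <- cons
  out <- out + t(out)
  out
}

#' Run the full inference ensemble and return the consensus network
#'
#' @param expr numeric matrix, genes x samples.
#' @param grid ensemble grid from [ensemble_grid()].
#' @param bins,eps passed to [infer_adjacency()].
#' @param n_keep passed to [consensus_network()].
#' @return consensus weighted adjacency matrix.
#' @export
infer_consensus <- function(expr, grid = ensemble_grid(), bins = NULL,
                            eps = 0, n_keep = NULL) {
  # one association matrix per estimator/discretizer, shared by the
  # three inference algorithms
  keys <- paste(grid$estimator, ifelse(is.na(grid$discretizer), "",
                                       grid$discretizer))
  cache <- new.env(parent = emptyenv())
  nets <- lapply(seq_len(nrow(grid)), function(i) {
    if (is.null(cache[[keys[i]]])) {
      cache[[keys[i]]] <- association_matrix(
        expr, grid$estimator[i],
        if (is.na(grid$discretizer[i])) "equal_freq" else grid$discretizer[i],
        bins)
    }
    assoc <- cache[[keys[i]]]
    out <- switch(grid$algorithm[i],
      clr = clr_transform(assoc),
      aracne = aracne_prune(assoc, eps = eps),
      mrnet = mrnet_scores(assoc))
    diag(out) <- 0
    rescale_minmax((out + t(out)) / 2)
  })
  consensus_network(nets, n_keep = n_keep)
}

#' Rank hub genes by Borda aggregation of centralities and significance
#'
#' Six ranked lists are aggregated: weighted degree (strength), mean
#' shortest-path distance to reachable nodes (ascending = more central),
#' betweenness, closeness, eigenvector centrality, and the significance
#' score.  Path-based measures use the distance transform
#' `1 - weight + 1e-6`.  The Borda consensus score of a node is the mean of
#' its (average-tie) ranks across the six lists; the final consensus rank
#' sorts ascending by that mean with lexicographic gene-id tie-breaking.
#'
#' Centralities are computed per connected component where applicable;
#' isolated nodes receive the worst values.  Genes absent from `ss` get the
#' worst significance rank with a warning.
#'
#' @param net weighted adjacency matrix.
#' @param ss named numeric vector of significance scores.
#' @return data frame (`node_ranking`): `gene_id`, `consensus_rank`,
#'   `borda_score` and the six per-measure ranks, sorted by consensus rank.
#' @export
rank_hub_genes <- function(net, ss) {
  ids <- rownames(net)
  g <- weighted_to_igraph(net)
  w <- igraph::E(g)$weight
  dist_w <- 1 - w + 1e-6

  strength <- igraph::strength(g)
  D <- igraph::distances(g, weights = dist_w)
  diag(D) <- NA
  mean_sp <- apply(D, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0L) Inf else mean(r)
  })
  btw <- igraph::betweenness(g, weights = dist_w)
  cls <- suppressWarnings(igraph::closeness(g, weights = dist_w))
  cls[!is.finite(cls)] <- 0
  eig <- igraph::eigen_centrality(g, weights = w)$vector

  ssv <- ss[ids]
  if (anyNA(ssv)) {
    warning(sum(is.na(ssv)), " node(s) missing a significance score; assigned worst rank",
            call. = FALSE)
    ssv[is.na(ssv)] <- -Inf
  }

  rk <- cbind(
    degree = rank(-strength, ties.method = "average"),
    shortest_path = rank(mean_sp, ties.method = "average"),
    betweenness = rank(-btw, ties.method = "average"),
    closeness = rank(-cls, ties.method = "average"),
    eigenvector = rank(-eig, ties.method = "average"),
    ss = rank(-ssv, ties.method = "average")
  )
  borda <- rowMeans(rk)
  cons <- integer(length(ids))
  cons[order(borda, ids, method = "radix")] <- seq_along(ids)
  out <- data.frame(gene_id = ids, consensus_rank = cons, borda_score = borda,
                    rank_degree = rk[, "degree"],
                    rank_shortest_path = rk[, "shortest_path"],
                    rank_betweenness = rk[, "betweenness"],
                    rank_closeness = rk[, "closeness"],
                    rank_eigenvector = rk[, "eigenvector"],
                    rank_ss = rk[, "ss"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$consensus_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("node_ranking", "data.frame")
  out
}
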