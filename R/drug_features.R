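#' Drug record
#'
#' A library entry: identifier, SMILES string, target gene set and (for
#' mechanism-of-action inference) a replicate perturbational expression
#' matrix over a shared landmark gene panel.
#'
#' @param drug_id unique identifier.
#' @param smiles SMILES string (compared by raw edit distance; no
#'   canonicalization).
#' @param targets character vector of target gene ids.
#' @param moa_profiles numeric matrix genes x replicates, or `NULL`.
#' @return object of class `drug_record`.
#' @export
drug_record <- function(drug_id, smiles, targets, moa_profiles = NULL) {
  structure(list(drug_id = drug_id, smiles = smiles,
                 targets = unique(as.character(targets)),
                 moa_profiles = moa_profiles),
            class = "drug_record")
}

#' Infer mechanism-of-action networks for a drug library
#'
#' Per drug with at least `min_replicates` perturbational replicates
#' (default 6, i.e. more than five), a consensus co-expression network over
#' the replicate profiles is inferred with the same ensemble used for the
#' disease network.  Drugs below the replicate threshold are excluded and
#' reported.
#'
#' @param drugs list of [drug_record()] objects.
#' @param min_replicates minimum replicate count.
#' @param grid,n_keep passed to [infer_consensus()].
#' @return list with `networks` (map drug_id -> adjacency matrix) and
#'   `excluded` (data frame of drug_id, reason).
#' @export
build_moa_networks <- function(drugs, min_replicates = 6L,
                               grid = ensemble_grid(), n_keep = NULL) {
  excluded <- data.frame(drug_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  nets <- list()
  panel <- NULL
  for (d in drugs) {
    if (is.null(d$moa_profiles) || ncol(d$moa_profiles) < min_replicates) {
      excluded <- rbind(excluded, data.frame(
        drug_id = d$drug_id,
        reason = sprintf("only %d replicate profiles (need >= %d)",
                         if (is.null(d$moa_profiles)) 0L else ncol(d$moa_profiles),
                         min_replicates),
        stringsAsFactors = FALSE))
      next
    }
    if (is.null(panel)) {
      panel <- rownames(d$moa_profiles)
    } else if (!identical(rownames(d$moa_profiles), panel)) {
      stop2("drug ", d$drug_id, " uses a different landmark gene panel")
    }
    nets[[d$drug_id]] <- suppressWarnings(
      infer_consensus(d$moa_profiles, grid = grid, n_keep = n_keep))
  }
  if (length(nets) == 0L) stop2("no drug passed the replicate filter")
  if (nrow(excluded) > 0L) {
    log_msg("excluded ", nrow(excluded), " drug(s) from MOA inference")
  }
  list(networks = nets, excluded = excluded)
}

#' Levenshtein edit distance between SMILES strings
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions; computed on the raw strings exactly as retrieved.
#'
#' @param s1,s2 character strings (vectorized; recycled to common length).
#' @return non-negative integer vector of edit distances.
#' @export
smiles_distance <- function(s1, s2) {
  as.integer(diag(utils::adist(s1, s2)))
}

#' Mean shortest-path distance between two target sets
#'
#' Mean over all cross pairs `(g1 in t1, g2 in t2)` of the unweighted
#' (hop-count) shortest-path length in the disease network.  Pairs in
#' different components contribute a penalty of `|V|` (finite, larger than
#' any realizable path); a gene paired with itself contributes 0.  Both
#' target sets must already be intersected with the network node set.
#'
#' @param net weighted adjacency matrix (topology only is used).
#' @param t1,t2 character vectors of gene ids present in `net`.
#' @return non-negative real.
#' @export
target_path_distance <- function(net, t1, t2) {
  sp <- target_sp_matrix(net)
  target_path_from_sp(sp, t1, t2)
}

# hop-count distance matrix with the |V| penalty applied
target_sp_matrix <- function(net) {
  g <- weighted_to_igraph(net)
  d <- igraph::distances(g, weights = NA)
  d[is.infinite(d)] <- nrow(net)
  d
}

target_path_from_sp <- function(sp, t1, t2) {
  if (length(t1) == 0L || length(t2) == 0L) {
    stop2("empty mapped target set (drug should have been excluded upstream)")
  }
  missing <- setdiff(c(t1, t2), rownames(sp))
  if (length(missing)) stop2("targets not in network: ", paste(missing, collapse = ", "))
  mean(sp[t1, t2, drop = FALSE])
}

#' Network effect score of a drug
#'
#' `ES = N_t / M_R`, where `N_t` is the number of targets mapped into the
#' disease network and `M_R` the median consensus (Borda) rank of those
#' targets — small median rank means central, strongly deregulated targets,
#' giving a large score.
#'
#' @param targets character vector of target gene ids (already mapped).
#' @param ranking a `node_ranking` data frame from [rank_hub_genes()].
#' @return positive real.
#' @export
effect_score <- function(targets, ranking) {
  rk <- ranking$consensus_rank[match(targets, ranking$gene_id)]
  rk <- rk[!is.na(rk)]
  if (length(rk) == 0L) stop2("no target present in the ranking")
  length(rk) / median(rk)
}

#' Build the four drug feature tables for the optimizer
#'
#' For the drugs that pass the replicate filter and have at least one
#' target mapped into the disease network, computes:
#'
#' * `him`: pairwise HIM distances between MOA networks;
#' * `lev`: pairwise Levenshtein distances between SMILES strings;
#' * `sp`: pairwise mean shortest-path distances between target sets;
#' * `es`: per-drug effect scores.
#'
#' Matrices are symmetric with zero diagonal; dropped drugs are reported
#' with a reason.
#'
#' @param drugs list of [drug_record()] objects.
#' @param disease_net filtered disease network adjacency matrix.
#' @param ranking `node_ranking` from [rank_hub_genes()] over `disease_net`.
#' @param min_replicates replicate threshold for MOA inference.
#' @param moa_grid,moa_n_keep ensemble settings for MOA inference.
#' @param moa_networks optional precomputed result of
#'   [build_moa_networks()] to avoid re-inference.
#' @return object of class `drug_feature_tables`: list with `drug_ids`,
#'   `him`, `lev`, `sp`, `es`, `targets` (mapped target sets) and
#'   `excluded`.
#' @export
build_feature_tables <- function(drugs, disease_net, ranking,
                                 min_replicates = 6L,
                                 moa_grid = ensemble_grid(),
                                 moa_n_keep = NULL,
                                 moa_networks = NULL) {
  names(drugs) <- vapply(drugs, function(d) d$drug_id, character(1))
  if (anyDuplicated(names(drugs))) stop2("duplicate drug ids")
  if (is.null(moa_networks)) {
    moa_networks <- build_moa_networks(drugs, min_replicates = min_replicates,
                                       grid = moa_grid, n_keep = moa_n_keep)
  }
  excluded <- moa_networks$excluded
  nets <- moa_networks$networks

  nodes <- rownames(disease_net)
  mapped <- lapply(drugs, function(d) intersect(d$targets, nodes))
  keep <- names(drugs)[names(drugs) %in% names(nets) &
                         vapply(mapped, length, integer(1)) > 0L]
  no_target <- setdiff(names(nets), keep)
  if (length(no_target)) {
    excluded <- rbind(excluded, data.frame(
      drug_id = no_target, reason = "no target mapped into the disease network",
      stringsAsFactors = FALSE))
  }
  if (length(keep) < 2L) stop2("fewer than 2 drugs usable for the optimizer")

  him <- him_matrix(nets[keep])
  lev <- utils::adist(vapply(drugs[keep], function(d) d$smiles, character(1)))
  dimnames(lev) <- list(keep, keep)
  spm <- target_sp_matrix(disease_net)
  k <- length(keep)
  sp <- matrix(0, k, k, dimnames = list(keep, keep))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- target_path_from_sp(spm, mapped[[keep[i]]], mapped[[keep[j]]])
      sp[i, j] <- sp[j, i] <- v
    }
  }
  diag(sp) <- 0  # diagonal unused by the objectives
  es <- vapply(keep, function(id) effect_score(mapped[[id]], ranking), numeric(1))

  structure(list(drug_ids = keep, him = him, lev = lev, sp = sp, es = es,
                 targets = mapped[keep], excluded = excluded),
            class = "drug_feature_tables")
}

#' @export
print.drug_feature_tables <- function(x, ...) {
  cat(sprintf("drug_feature_tables: %d drugs (%d excluded)\n",
              length(x$drug_ids), nrow(x$excluded)))
  invisible(x)
}

#' Read a drug library from TSV files
#'
#' The drug table has columns `drug_id`, `smiles`, `targets`
#' (comma-separated).  The optional MOA manifest maps `drug_id` to a
#' genes x replicates TSV (first column `gene_id`).
#'
#' @param drug_path drug table TSV.
#' @param moa_manifest optional YAML manifest (list of `drug_id`, `file`)
#'   or a named list.
#' @param base_dir directory for relative MOA profile paths.
#' @return list of [drug_record()] objects.
#' @export
read_drug_table <- function(drug_path, moa_manifest = NULL, base_dir = NULL) {
  df <- utils::read.delim(drug_path, stringsAsFactors = FALSE)
  profiles <- list()
  if (!is.null(moa_manifest)) {
    if (is.character(moa_manifest)) {
      if (is.null(base_dir)) base_dir <- dirname(moa_manifest)
      moa_manifest <- yaml::read_yaml(moa_manifest)
    }
    base_dir <- base_dir %||% "."
    for (m in moa_manifest) {
      path <- m$file
      if (!file.exists(path)) path <- file.path(base_dir, m$file)
      p <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
      mat <- as.matrix(p[, -1, drop = FALSE])
      rownames(mat) <- p[[1]]
      profiles[[m$drug_id]] <- mat
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    drug_record(df$drug_id[i], df$smiles[i],
                strsplit(df$targets[i], ",", fixed = TRUE)[[1]],
                moa_profiles = profiles[[df$drug_id[i]]])
  })
}

#' Export feature tables as TSV matrices plus JSON metadata
#'
#' @param feats a `drug_feature_tables` object.
#' @param dir output directory (created if needed).
#' @export
write_feature_tables <- function(feats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    data.frame(drug_id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm(feats$him, "him.tsv"); wm(feats$lev, "lev.tsv"); wm(feats$sp, "sp.tsv")
  utils::write.table(data.frame(drug_id = feats$drug_ids, es = feats$es),
                     file.path(dir, "es.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(excluded = feats$excluded,
         targets = feats$targets),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
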