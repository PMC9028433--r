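#' Pipeline configuration
#'
#' Validates a configuration list (typically parsed from YAML).  Unknown
#' keys are rejected so typos fail fast.
#'
#' @param config named list or path to a YAML file.
#' @param base_dir directory against which relative input paths resolve;
#'   defaults to the config file's directory when `config` is a path.
#' @return validated configuration list with defaults filled in.
#' @export
pipeline_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    expression = NULL, sample_meta = NULL,
    drug_table = NULL, moa_manifest = NULL, layer_manifest = NULL,
    out_dir = "run", seed = 1L,
    min_pairs = 10L, top_fraction = 0.10,
    consensus_n_keep = NULL, min_replicates = 6L,
    ga = list(), n_runs = 10L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop2("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  ga_unknown <- setdiff(names(cfg$ga), names(ga_config()))
  if (length(ga_unknown)) stop2("unknown ga config keys: ", paste(ga_unknown, collapse = ", "))
  for (f in c("expression", "sample_meta", "drug_table", "layer_manifest")) {
    if (is.null(cfg[[f]])) stop2("config field '", f, "' is required")
  }
  if (!is.null(base_dir)) {
    for (f in c("expression", "sample_meta", "drug_table", "moa_manifest",
                "layer_manifest", "out_dir")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        cfg[[f]] <- file.path(base_dir, cfg[[f]])
      }
    }
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("pipeline aborted at stage '", name, "': ", conditionMessage(e))
  })
}

#' Run the full drug-combination pipeline
#'
#' Executes candidate-gene scoring, consensus co-expression inference on
#' the selected genes, prior construction and filtering, Borda hub
#' ranking, drug feature computation, multi-objective optimization and the
#' stability analysis, writing every intermediate artifact plus a run
#' manifest to `out_dir`.  One global seed drives all randomness, so a
#' re-run with the same configuration reproduces all outputs.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @return the output directory, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  set.seed(cfg$seed)  # covers ARPACK-based centralities as well as the GA
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  expr <- stage("read_expression",
                read_expression_tsv(cfg$expression, cfg$sample_meta,
                                    min_pairs = cfg$min_pairs))

  scores <- stage("score_genes", suppressWarnings(
    score_genes(expr, fraction = cfg$top_fraction)))
  write_gene_scores_tsv(scores, out("gene_scores.tsv"))
  selected <- select_candidate_genes(scores, cfg$top_fraction)

  coexpr <- stage("infer_network", {
    sub <- log2(expr$values[selected, , drop = FALSE] + 1)
    suppressWarnings(infer_consensus(sub, n_keep = cfg$consensus_n_keep))
  })
  write_edge_tsv(adjacency_to_edges(coexpr), out("disease_network.tsv"))

  prior <- stage("build_prior", {
    layers <- read_layer_manifest(cfg$layer_manifest)
    build_prior_network(layers)
  })
  write_edge_tsv(prior$edges, out("prior_network.tsv"))

  filtered <- stage("filter_network", filter_disease_network(coexpr, prior))
  write_edge_tsv(adjacency_to_edges(filtered), out("filtered_network.tsv"))

  ranking <- stage("rank_hubs", {
    ss <- setNames(pmax(scores$SS_wilcoxon, scores$SS_ftest), scores$gene_id)
    rank_hub_genes(filtered, ss)
  })
  utils::write.table(ranking, out("hub_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  feats <- stage("drug_features", {
    drugs <- read_drug_table(cfg$drug_table, cfg$moa_manifest)
    build_feature_tables(drugs, filtered, ranking,
                         min_replicates = cfg$min_replicates)
  })
  write_feature_tables(feats, out("features"))

  ga_cfg <- do.call(ga_config, cfg$ga)
  state <- stage("optimize", run_optimizer(feats, ga_cfg, seed = cfg$seed))
  write_hof_json(state, out("hof.json"))
  utils::write.table(state$traces, out("traces.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stab <- stage("stability",
                stability_analysis(feats, ga_cfg, n_runs = cfg$n_runs,
                                   seed = cfg$seed))
  write_edge_tsv(stab$frequency_edges, out("frequency_network.tsv"))
  utils::write.table(stab$hof_combinations, out("stability_hofs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "drugcombinet",
    version = as.character(utils::packageVersion("drugcombinet")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "ga")],
    ga = ga_cfg,
    parameter_hash = paste(utils::head(
      unlist(lapply(cfg, function(x) paste(deparse(x), collapse = ""))), 50),
      collapse = "|"))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the default synthetic study and writes the files the pipeline
#' consumes: expression and sample-metadata TSVs, the drug table with its
#' MOA profile manifest, the prior-layer manifest, a ready-to-run pipeline
#' config, and the ground-truth JSON.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param G,pairs,K generator sizes (see the simulators).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, G = 300L, pairs = 20L,
                                 K = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- build_default_fixture(seed = seed, K = K, G = G, pairs = pairs)

  expr_df <- data.frame(gene_id = rownames(fx$expr$values), fx$expr$values,
                        check.names = FALSE)
  utils::write.table(expr_df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$expr$sample_meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  drug_df <- data.frame(
    drug_id = vapply(fx$library, function(d) d$drug_id, character(1)),
    smiles = vapply(fx$library, function(d) d$smiles, character(1)),
    targets = vapply(fx$library, function(d) paste(d$targets, collapse = ","),
                     character(1)))
  utils::write.table(drug_df, file.path(dir, "drugs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  dir.create(file.path(dir, "moa"), showWarnings = FALSE)
  moa_manifest <- lapply(fx$library, function(d) {
    f <- file.path("moa", paste0(d$drug_id, ".tsv"))
    utils::write.table(
      data.frame(gene_id = rownames(d$moa_profiles), d$moa_profiles,
                 check.names = FALSE),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    list(drug_id = d$drug_id, file = f)
  })
  yaml::write_yaml(moa_manifest, file.path(dir, "moa_manifest.yaml"))

  dir.create(file.path(dir, "layers"), showWarnings = FALSE)
  layers <- simulate_prior_layers(fx$truth$truth_network, seed = seed + 1L)
  layer_manifest <- lapply(layers, function(l) {
    f <- file.path("layers", paste0(l$source_name, ".tsv"))
    utils::write.table(l$associations, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(name = l$source_name, file = f, type = l$type, category = l$category)
  })
  yaml::write_yaml(layer_manifest, file.path(dir, "layer_manifest.yaml"))

  jsonlite::write_json(
    list(planted_de_genes = fx$truth$planted_de_genes,
         planted_var_genes = fx$truth$planted_var_genes,
         planted_combination = fx$truth$planted_combination),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

  yaml::write_yaml(list(expression = "expression.tsv",
                        sample_meta = "sample_meta.tsv",
                        drug_table = "drugs.tsv",
                        moa_manifest = "moa_manifest.yaml",
                        layer_manifest = "layer_manifest.yaml",
                        out_dir = "run", seed = seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
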