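#' Prior-knowledge association layer
#'
#' A layer is a single evidence source: either a gene-gene edge list
#' (`type = "edges"`) or a gene-term bipartite annotation list
#' (`type = "bipartite"`), tagged with one of the three evidence categories
#' `Interaction`, `Regulation`, `Functional`.
#'
#' @param source_name short identifier of the source.
#' @param category one of `"Interaction"`, `"Regulation"`, `"Functional"`.
#' @param associations 2-column data frame; for `edges` both columns are
#'   genes, for `bipartite` the first column is a gene and the second a term.
#' @param type `"edges"` or `"bipartite"`.
#' @return object of class `prior_layer`.
#' @export
prior_layer <- function(source_name, category, associations,
                        type = c("edges", "bipartite")) {
  type <- match.arg(type)
  if (!category %in% c("Interaction", "Regulation", "Functional")) {
    stop2("category must be Interaction, Regulation or Functional")
  }
  if (ncol(associations) < 2L) stop2("associations need 2 columns")
  assoc <- data.frame(a = as.character(associations[[1]]),
                      b = as.character(associations[[2]]),
                      stringsAsFactors = FALSE)
  assoc <- unique(assoc)
  structure(list(source_name = source_name, category = category,
                 associations = assoc, type = type),
            class = "prior_layer")
}

#' Project a prior layer to a binary gene-gene network
#'
#' Bipartite (gene-term) layers are projected onto genes by shared
#' membership: two genes are connected iff they share at least one term
#' (e.g. they are annotated to the same pathway).  Gene-gene layers pass
#' through after symmetrization and deduplication (set
#' `project_gene_gene = TRUE` to instead connect genes sharing a common
#' interaction partner).
#'
#' @param layer a [prior_layer()].
#' @param project_gene_gene also apply the common-neighbor projection to
#'   gene-gene layers?
#' @return a [binary_network()].
#' @export
project_layer <- function(layer, project_gene_gene = FALSE) {
  assoc <- layer$associations
  if (nrow(assoc) == 0L) {
    warning("empty layer '", layer$source_name, "'", call. = FALSE)
    return(binary_network())
  }
  if (layer$type == "edges" && !project_gene_gene) {
    return(binary_network(assoc))
  }
  # shared-association projection: connect genes with a common right-hand item
  by_term <- split(assoc$a, assoc$b)
  pairs <- lapply(by_term, function(genes) {
    genes <- unique(genes)
    if (length(genes) < 2L) return(NULL)
    cmb <- utils::combn(sort(genes), 2L)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  binary_network(pairs, nodes = unique(assoc$a))
}

#' Merge the layers of one category by edge-set union
#'
#' @param layers list of [binary_network()] objects from one category.
#' @return a [binary_network()] whose edge set (and node set) is the union.
#' @export
merge_category <- function(layers) {
  if (length(layers) == 0L) return(binary_network())
  ed <- do.call(rbind, lapply(layers, function(l) l$edges))
  nodes <- unique(unlist(lapply(layers, function(l) l$nodes)))
  binary_network(ed, nodes = nodes)
}

#' Intersect the three category networks into the final prior
#'
#' An edge survives iff it is present in the Interaction, Regulation and
#' Functional merged networks; the node set is restricted to the endpoints
#' of surviving edges.
#'
#' @param interaction,regulation,functional [binary_network()] objects.
#' @return a [binary_network()].
#' @export
intersect_categories <- function(interaction, regulation, functional) {
  k1 <- edge_keys(interaction)
  keep <- k1 %in% edge_keys(regulation) & k1 %in% edge_keys(functional)
  ed <- interaction$edges[keep, , drop = FALSE]
  if (nrow(ed) == 0L) {
    warning("prior-category intersection is EMPTY: downstream filtering will erase the disease network",
            call. = FALSE)
  }
  binary_network(ed)
}

#' Build the final multilayer prior from a list of layers
#'
#' Projects every layer, merges layers within each of the three categories
#' by union, and intersects the three category networks.
#'
#' @param layers list of [prior_layer()] objects covering all three
#'   categories.
#' @param project_gene_gene passed to [project_layer()].
#' @return a [binary_network()].
#' @export
build_prior_network <- function(layers, project_gene_gene = FALSE) {
  cats <- vapply(layers, function(l) l$category, character(1))
  missing <- setdiff(c("Interaction", "Regulation", "Functional"), cats)
  if (length(missing)) {
    stop2("no layer for categories: ", paste(missing, collapse = ", "))
  }
  merged <- lapply(c("Interaction", "Regulation", "Functional"), function(cat) {
    merge_category(lapply(layers[cats == cat], project_layer,
                          project_gene_gene = project_gene_gene))
  })
  intersect_categories(merged[[1]], merged[[2]], merged[[3]])
}

#' Filter a co-expression network by the prior
#'
#' Keeps a co-expression edge iff the same unordered gene pair is present in
#' the prior; weights are preserved and isolated nodes are retained.  Warns
#' when less than 1% of the co-expression edges find support (a symptom of
#' an identifier-namespace mismatch).
#'
#' @param coexpr weighted adjacency matrix.
#' @param prior a [binary_network()].
#' @return filtered weighted adjacency matrix over the same node set.
#' @export
filter_disease_network <- function(coexpr, prior) {
  ed <- adjacency_to_edges(coexpr)
  if (nrow(ed) > 0L) {
    supported <- edge_key(ed$gene_a, ed$gene_b) %in% edge_keys(prior)
    if (mean(supported) < 0.01) {
      warning(sprintf("only %d/%d co-expression edges supported by the prior (namespace mismatch?)",
                      sum(supported), nrow(ed)), call. = FALSE)
    }
    ed <- ed[supported, , drop = FALSE]
  }
  edges_to_adjacency(ed, nodes = rownames(coexpr))
}

#' Read prior layers from a manifest
#'
#' The manifest is a YAML (or equivalently structured list) with one entry
#' per layer: `name`, `file` (2-column TSV), `type` (`edges`/`bipartite`)
#' and `category`.
#'
#' @param manifest path to a YAML manifest or an already-parsed list.
#' @param base_dir directory against which relative layer paths resolve.
#' @return list of [prior_layer()] objects.
#' @export
read_layer_manifest <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  base_dir <- base_dir %||% "."
  lapply(manifest, function(m) {
    path <- m$file
    if (!file.exists(path)) path <- file.path(base_dir, m$file)
    assoc <- utils::read.delim(path, stringsAsFactors = FALSE)
    prior_layer(m$name %||% basename(path), m$category, assoc, type = m$type)
  })
}
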