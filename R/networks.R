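#' Weighted and binary gene networks
#'
#' Two lightweight containers are used throughout the pipeline:
#'
#' * a *weighted network* is a symmetric numeric adjacency matrix with zero
#'   diagonal, weights in `[0, 1]` and gene identifiers as dimnames — the
#'   output of co-expression inference and the object compared by the
#'   Hamming-Ipsen-Mikhailov distance;
#' * a *binary network* is an unweighted undirected edge set (class
#'   `binary_network`), used for the prior-knowledge layers.
#'
#' @param mat square numeric matrix; dimnames give the gene ids.
#' @return `as_weighted_network()` returns the validated matrix.
#' @export
as_weighted_network <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop2("adjacency must be a numeric matrix")
  if (nrow(mat) != ncol(mat)) stop2("adjacency must be square")
  if (is.null(rownames(mat))) stop2("adjacency must carry gene ids as dimnames")
  if (!identical(rownames(mat), colnames(mat))) stop2("row and column gene ids differ")
  if (anyDuplicated(rownames(mat))) stop2("duplicate gene ids")
  if (any(!is.finite(mat))) stop2("non-finite weights")
  if (max(abs(mat - t(mat))) > 1e-12) stop2("adjacency must be symmetric")
  if (any(diag(mat) != 0)) stop2("self-loops are not allowed")
  if (min(mat) < 0 || max(mat) > 1) stop2("weights must lie in [0, 1]")
  mat
}

#' Construct a binary (unweighted, undirected) network
#'
#' Edges are stored canonically (`gene_a < gene_b`), deduplicated, with
#' self-loops removed.  `nodes` may extend beyond edge endpoints to keep
#' isolated nodes.
#'
#' @param edges data frame whose first two columns are gene ids, or NULL.
#' @param nodes optional character vector of node ids.
#' @return object of class `binary_network` with elements `nodes` and
#'   `edges` (data frame `gene_a`, `gene_b`).
#' @export
binary_network <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0) {
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    ed <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                     stringsAsFactors = FALSE)
    ed <- unique(ed)
    ed <- ed[order(ed$gene_a, ed$gene_b, method = "radix"), , drop = FALSE]
    rownames(ed) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), ed$gene_a, ed$gene_b)))
  structure(list(nodes = nodes, edges = ed), class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) edge_key(net$edges$gene_a, net$edges$gene_b)

#' Convert a weighted adjacency matrix to an edge list
#'
#' @param mat weighted network adjacency (see [as_weighted_network()]).
#' @param keep_zero keep zero-weight pairs as well?
#' @return data frame with columns `gene_a`, `gene_b`, `weight`,
#'   one row per unordered pair, `gene_a < gene_b`.
#' @export
adjacency_to_edges <- function(mat, keep_zero = FALSE) {
  ids <- rownames(mat)
  ut <- upper.tri(mat)
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                   weight = mat[ut], stringsAsFactors = FALSE)
  sw <- df$gene_a > df$gene_b
  if (any(sw)) {
    tmp <- df$gene_a[sw]; df$gene_a[sw] <- df$gene_b[sw]; df$gene_b[sw] <- tmp
  }
  if (!keep_zero) df <- df[df$weight > 0, , drop = FALSE]
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Convert an edge list to a weighted adjacency matrix
#'
#' @param edges data frame `gene_a`, `gene_b`, `weight` (weight defaults to 1).
#' @param nodes node universe (defaults to edge endpoints).
#' @return symmetric adjacency matrix with `nodes` as dimnames.
#' @export
edges_to_adjacency <- function(edges, nodes = NULL) {
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(a))
  nodes <- sort(unique(c(nodes, a, b)))
  mat <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(a, nodes); ib <- match(b, nodes)
  mat[cbind(ia, ib)] <- w
  mat[cbind(ib, ia)] <- w
  diag(mat) <- 0
  mat
}

weighted_to_igraph <- function(mat) {
  igraph::graph_from_adjacency_matrix(mat, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Read / write edge-list TSV files
#'
#' Plain 3-column (`gene_a`, `gene_b`, `weight`) or 2-column TSV with header.
#'
#' @param path file path.
#' @param edges data frame as produced by [adjacency_to_edges()].
#' @name edge_tsv
#' @export
read_edge_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname edge_tsv
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
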