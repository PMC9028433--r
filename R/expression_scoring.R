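#' Paired expression container
#'
#' Bundles a non-negative expression matrix (genes x samples) with per-sample
#' metadata for a paired disease/control design.  Every subject must appear
#' exactly once per condition; columns of `values` are matched to
#' `sample_meta$sample_id`.
#'
#' @param values numeric matrix, genes x samples, non-negative, rownames are
#'   unique gene ids, colnames are sample ids.
#' @param sample_meta data frame with columns `sample_id`, `subject_id`,
#'   `condition` (values `"disease"` / `"control"`).
#' @param min_pairs minimum number of matched subject pairs required
#'   (an input-quality gate for real cohorts; relax for toy data).
#' @return object of class `expression_set` with elements `values`,
#'   `sample_meta`, and `pairs` (subject-ordered disease/control column
#'   indices).
#' @export
expression_set <- function(values, sample_meta, min_pairs = 2L) {
  if (!is.matrix(values) || !is.numeric(values)) stop2("values must be a numeric matrix")
  if (is.null(rownames(values))) stop2("values must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop2("duplicate gene ids")
  if (any(values < 0)) stop2("negative expression values")
  req <- c("sample_id", "subject_id", "condition")
  if (!all(req %in% names(sample_meta))) {
    stop2("sample_meta needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(sample_meta$condition %in% c("disease", "control"))) {
    stop2("condition must be 'disease' or 'control'")
  }
  if (is.null(colnames(values))) stop2("values must have sample ids as colnames")
  if (!setequal(colnames(values), sample_meta$sample_id) ||
      anyDuplicated(sample_meta$sample_id)) {
    stop2("sample_meta$sample_id must match the columns of values")
  }
  tab <- table(sample_meta$subject_id, sample_meta$condition)
  if (!all(tab == 1L)) {
    bad <- rownames(tab)[rowSums(tab == 1L) != 2L]
    stop2("pairing error: subjects without exactly one sample per condition: ",
          paste(bad, collapse = ", "))
  }
  subjects <- sort(unique(sample_meta$subject_id))
  if (length(subjects) < min_pairs) {
    stop2("paired design requires at least ", min_pairs, " matched subjects, got ",
          length(subjects))
  }
  meta <- sample_meta[match(sample_meta$sample_id, sample_meta$sample_id), ]
  col_of <- function(cond) {
    sid <- meta$sample_id[match(paste(subjects, cond),
                                paste(meta$subject_id, meta$condition))]
    match(sid, colnames(values))
  }
  pairs <- data.frame(subject_id = subjects,
                      disease = col_of("disease"),
                      control = col_of("control"),
                      stringsAsFactors = FALSE)
  structure(list(values = values, sample_meta = sample_meta, pairs = pairs),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes, %d matched pairs\n",
              nrow(x$values), nrow(x$pairs)))
  invisible(x)
}

# log2(v + 1) matrices split by condition, columns in subject order
log2_split <- function(expr) {
  list(disease = log2(expr$values[, expr$pairs$disease, drop = FALSE] + 1),
       control = log2(expr$values[, expr$pairs$control, drop = FALSE] + 1))
}

#' Per-gene paired log2 fold change
#'
#' `logFC = mean(log2(v + 1) | disease) - mean(log2(v + 1) | control)`.
#' The pseudocount guards against zeros in FPKM-like inputs.
#'
#' @param expr an [expression_set()].
#' @return named numeric vector of log2 fold changes.
#' @export
compute_paired_logfc <- function(expr) {
  lg <- log2_split(expr)
  rowMeans(lg$disease) - rowMeans(lg$control)
}

#' Paired Wilcoxon signed-rank test per gene
#'
#' Two-sided signed-rank test on per-subject `disease - control` differences
#' of `log2(v + 1)` expression.  Zero differences are removed; the exact null
#' distribution is used for up to 25 remaining pairs when there are no ties
#' in the absolute differences, otherwise the normal approximation with
#' continuity correction.  Genes whose differences are all zero get `p = 1`
#' with a warning.
#'
#' @param expr an [expression_set()].
#' @param exact_max largest post-zero-removal pair count for which the exact
#'   distribution is used.
#' @return named numeric vector of two-sided p-values in (0, 1].
#' @export
paired_wilcoxon <- function(expr, exact_max = 25L) {
  if (nrow(expr$pairs) < 2L) stop2("need at least 2 matched pairs")
  lg <- log2_split(expr)
  d <- lg$disease - lg$control
  degenerate <- character()
  p <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    di <- di[di != 0]
    n <- length(di)
    if (n == 0L) {
      degenerate <<- c(degenerate, rownames(d)[i])
      return(1)
    }
    exact <- n <= exact_max && !anyDuplicated(abs(di))
    pv <- suppressWarnings(
      stats::wilcox.test(di, mu = 0, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value
    )
    min(pv, 1)
  }, numeric(1))
  if (length(degenerate)) {
    warning(length(degenerate),
            " gene(s) with all-zero paired differences set to p = 1",
            call. = FALSE)
  }
  setNames(p, rownames(d))
}

#' Variance F-test per gene
#'
#' Two-sided F-test comparing disease vs control variance of `log2(v + 1)`
#' expression: `F = s2_disease / s2_control`,
#' `p = 2 * min(P(F <= f), P(F >= f))` under `F(n_d - 1, n_c - 1)`, capped at
#' 1.  Genes with zero variance in both groups get `p = 1`; zero variance in
#' exactly one group gives the smallest positive double (maximally
#' significant, kept positive so downstream log-scores stay finite).
#'
#' @param expr an [expression_set()].
#' @return named numeric vector of two-sided p-values in (0, 1].
#' @export
variance_f_test <- function(expr) {
  if (nrow(expr$pairs) < 3L) stop2("need at least 3 samples per condition")
  lg <- log2_split(expr)
  vd <- apply(lg$disease, 1, var)
  vc <- apply(lg$control, 1, var)
  df1 <- ncol(lg$disease) - 1L
  df2 <- ncol(lg$control) - 1L
  p <- numeric(length(vd))
  both0 <- vd == 0 & vc == 0
  one0 <- xor(vd == 0, vc == 0)
  ok <- !(both0 | one0)
  f <- vd[ok] / vc[ok]
  p[ok] <- pmin(1, 2 * pmin(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE)))
  p[both0] <- 1
  p[one0] <- .Machine$double.xmin
  if (any(both0)) warning(sum(both0), " gene(s) with zero variance in both groups set to p = 1",
                          call. = FALSE)
  if (any(one0)) warning(sum(one0), " gene(s) with zero variance in one group set to minimal p",
                         call. = FALSE)
  setNames(p, rownames(lg$disease))
}

#' Significance score combining effect size and p-value
#'
#' `SS = |logFC * (-log10 p)|`, computed separately for each test.  A
#' p-value of 1 or a zero fold change both give a score of 0; p-values must
#' be strictly positive (floor them upstream).
#'
#' @param logfc numeric vector of log2 fold changes.
#' @param pvals numeric vector of p-values in (0, 1].
#' @return non-negative numeric vector of scores.
#' @export
significance_scores <- function(logfc, pvals) {
  if (length(logfc) != length(pvals)) stop2("logfc and pvals lengths differ")
  if (any(pvals <= 0)) stop2("p-values must be > 0 (floor upstream)")
  if (any(pvals > 1)) stop2("p-values must be <= 1")
  abs(logfc * (-log10(pvals)))
}

#' Score all genes and rank both significance-score lists
#'
#' Runs the paired log fold change, the paired Wilcoxon test and the
#' variance F-test, combines each p-value vector with the fold change into a
#' significance score, and ranks both score lists descending (rank 1 =
#' highest score; ties broken lexicographically by gene id).
#'
#' @param expr an [expression_set()].
#' @param fraction top fraction of each ranked list flagged as selected.
#' @return data frame (gene score table) with columns `gene_id`, `logFC`,
#'   `p_wilcoxon`, `p_ftest`, `SS_wilcoxon`, `SS_ftest`, `rank_wilcoxon`,
#'   `rank_ftest`, `selected`.
#' @export
score_genes <- function(expr, fraction = 0.10) {
  lfc <- compute_paired_logfc(expr)
  pw <- paired_wilcoxon(expr)
  pfv <- variance_f_test(expr)
  ids <- rownames(expr$values)
  ssw <- significance_scores(lfc, pw)
  ssf <- significance_scores(lfc, pfv)
  tab <- data.frame(gene_id = ids,
                    logFC = unname(lfc),
                    p_wilcoxon = unname(pw),
                    p_ftest = unname(pfv),
                    SS_wilcoxon = unname(ssw),
                    SS_ftest = unname(ssf),
                    rank_wilcoxon = rank_desc_lex(ssw, ids),
                    rank_ftest = rank_desc_lex(ssf, ids),
                    stringsAsFactors = FALSE)
  sel <- select_candidate_genes(tab, fraction)
  tab$selected <- as.integer(tab$gene_id %in% sel)
  tab
}

#' Select candidate genes as the union of both top-ranked lists
#'
#' Takes the top `floor(fraction * G)` genes of the Wilcoxon-based and
#' F-test-based significance-score rankings and returns their union, so the
#' result has between `floor(fraction * G)` and `2 * floor(fraction * G)`
#' genes.
#'
#' @param table gene score table from [score_genes()] (needs `gene_id`,
#'   `rank_wilcoxon`, `rank_ftest`).
#' @param fraction real in (0, 1]; fraction of each list taken.
#' @return character vector of selected gene ids (sorted).
#' @export
select_candidate_genes <- function(table, fraction = 0.10) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop2("fraction must be a single value in (0, 1]")
  }
  g <- nrow(table)
  k <- floor(fraction * g)
  if (k < 1L) stop2("fraction too small: top list would be empty")
  top_w <- table$gene_id[table$rank_wilcoxon <= k]
  top_f <- table$gene_id[table$rank_ftest <= k]
  sort(union(top_w, top_f))
}

#' Read an expression bundle from TSV files
#'
#' @param expr_path genes x samples TSV, first column `gene_id`.
#' @param meta_path sample metadata TSV (`sample_id`, `subject_id`,
#'   `condition`).
#' @param min_pairs passed to [expression_set()]; real cohorts use 10.
#' @return an [expression_set()].
#' @export
read_expression_tsv <- function(expr_path, meta_path, min_pairs = 2L) {
  df <- utils::read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_set(mat, meta, min_pairs = min_pairs)
}

#' Write a gene score table as TSV
#'
#' @param table data frame from [score_genes()].
#' @param path output path.
#' @export
write_gene_scores_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
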