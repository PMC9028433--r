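# Independent oracles used across the suite.  These deliberately use
# naive, easily-audited algorithms (dynamic programming, enumeration,
# pairwise loops) rather than the package's own code paths.

# Levenshtein distance by the classic DP recurrence
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  }
  d[n + 1, m + 1]
}

# pairwise-loop dominance check (maximization)
dominates_oracle <- function(a, b) all(a >= b) && any(a > b)

# front assignment by repeated peeling with explicit pairwise loops
fronts_oracle <- function(objs) {
  n <- nrow(objs)
  front <- integer(n)
  assigned <- rep(FALSE, n)
  level <- 0L
  while (!all(assigned)) {
    level <- level + 1L
    this <- logical(n)
    for (i in which(!assigned)) {
      dominated <- FALSE
      for (j in which(!assigned)) {
        if (i != j && dominates_oracle(objs[j, ], objs[i, ])) {
          dominated <- TRUE; break
        }
      }
      if (!dominated) this[i] <- TRUE
    }
    front[this] <- level
    assigned[this] <- TRUE
  }
  front
}

front_of <- function(fronts, n) {
  out <- integer(n)
  for (k in seq_along(fronts)) out[fronts[[k]]] <- k
  out
}

# mean-rank Borda aggregation from explicitly materialized ranked lists
borda_oracle <- function(rank_lists, ids) {
  pos <- sapply(rank_lists, function(r) r[ids])
  mean_rank <- rowMeans(pos)
  ord <- order(mean_rank, ids)
  out <- integer(length(ids)); out[ord] <- seq_along(ids)
  names(out) <- ids
  out
}

# exact two-sided signed-rank p-value by enumerating all sign assignments,
# mirroring the conventional two-sided rule (double the smaller tail)
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_low <- mean(v_all <= v_obs)
  p_up <- mean(v_all >= v_obs)
  p <- if (v_obs > n * (n + 1) / 4) p_up else p_low
  min(2 * p, 1)
}

# random symmetric weighted adjacency in [0, 1]
random_adjacency <- function(n, density = 0.4, ids = sprintf("n%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(m)
  w <- runif(sum(ut))
  w[runif(sum(ut)) > density] <- 0
  m[ut] <- w
  m + t(m)
}

# tiny paired expression set from a disease and a control matrix
toy_expression <- function(disease, control, genes = NULL) {
  np <- ncol(disease)
  genes <- genes %||% sprintf("g%d", seq_len(nrow(disease)))
  subjects <- sprintf("s%d", seq_len(np))
  vals <- cbind(disease, control)
  rownames(vals) <- genes
  colnames(vals) <- c(paste0(subjects, "_d"), paste0(subjects, "_c"))
  meta <- data.frame(sample_id = colnames(vals),
                     subject_id = rep(subjects, 2),
                     condition = rep(c("disease", "control"), each = np))
  expression_set(vals, meta, min_pairs = 2L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
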