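#' NSGA-II machinery: dominance, non-dominated sorting, crowding distance
#'
#' All objectives are maximized.  Individual `i` dominates `j` iff `i` is
#' at least as good on every objective and strictly better on at least one.
#'
#' @param objs numeric matrix, individuals x objectives.
#' @return `dominance_matrix()`: logical matrix `D` with `D[i, j]` TRUE iff
#'   `i` dominates `j`.
#' @export
dominance_matrix <- function(objs) {
  n <- nrow(objs)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(objs))) {
    v <- objs[, k]
    ge <- ge & outer(v, v, ">=")
    gt <- gt | outer(v, v, ">")
  }
  ge & gt
}

#' @rdname dominance_matrix
#' @return `pareto_fronts()`: list of integer index vectors, front 1 first.
#' @export
pareto_fronts <- function(objs) {
  d <- dominance_matrix(objs)
  ndom <- colSums(d)
  fronts <- list()
  remaining <- rep(TRUE, nrow(objs))
  while (any(remaining)) {
    f <- which(remaining & ndom == 0L)
    fronts[[length(fronts) + 1L]] <- f
    remaining[f] <- FALSE
    if (any(remaining)) {
      ndom <- ndom - colSums(d[f, , drop = FALSE])
    }
  }
  fronts
}

#' @rdname dominance_matrix
#' @return `crowding_distance()`: numeric vector; boundary points per
#'   objective get `Inf`.
#' @export
crowding_distance <- function(objs) {
  n <- nrow(objs)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (k in seq_len(ncol(objs))) {
    v <- objs[, k]
    ord <- order(v, seq_len(n), method = "radix")
    cd[ord[c(1L, n)]] <- Inf
    rng <- v[ord[n]] - v[ord[1L]]
    if (rng > 0) {
      mid <- 2:(n - 1L)
      cd[ord[mid]] <- cd[ord[mid]] + (v[ord[mid + 1L]] - v[ord[mid - 1L]]) / rng
    }
  }
  cd
}

#' NSGA-II environmental selection
#'
#' Fast non-dominated sorting fills the next population front by front; the
#' first front that does not fit entirely is truncated by descending
#' crowding distance (ties broken by pool index, so selection is
#' deterministic).
#'
#' @param objs numeric matrix of the pooled individuals' objectives.
#' @param k number of individuals to select.
#' @return integer vector of `k` selected row indices.
#' @export
nsga2_select <- function(objs, k) {
  if (k > nrow(objs)) stop2("cannot select ", k, " from a pool of ", nrow(objs))
  fronts <- pareto_fronts(objs)
  sel <- integer(0)
  for (f in fronts) {
    if (length(sel) + length(f) <= k) {
      sel <- c(sel, f)
      if (length(sel) == k) break
    } else {
      cd <- crowding_distance(objs[f, , drop = FALSE])
      ord <- order(-cd, seq_along(f), method = "radix")
      sel <- c(sel, f[ord[seq_len(k - length(sel))]])
      break
    }
  }
  sel
}
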