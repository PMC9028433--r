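#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median pf quantile rbinom rnorm runif sd setNames
#'   var wilcox.test
#' @importFrom utils adist head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

#' Rank a numeric vector descending with lexicographic tie-breaking
#'
#' Returns a strict permutation of `1..n`: rank 1 is the largest value; ties
#' are broken by the lexicographic order of `ids` so that ranking is
#' reproducible bit-for-bit across platforms.
#'
#' @param x numeric vector.
#' @param ids character vector of the same length used to break ties.
#' @return integer vector of ranks (1 = highest `x`).
#' @keywords internal
rank_desc_lex <- function(x, ids) {
  stopifnot(length(x) == length(ids))
  ord <- order(-x, ids, method = "radix")
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

# canonical "a|b" key of an unordered gene pair
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
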