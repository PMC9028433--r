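#' Hamming-Ipsen-Mikhailov (HIM) distance between networks
#'
#' HIM combines a local edit term with a global spectral term for two
#' graphs on the same node set with weights in `[0, 1]`:
#'
#' * **Hamming** `H`: mean absolute adjacency difference over the
#'   `N (N - 1) / 2` unordered node pairs;
#' * **Ipsen-Mikhailov** `IM`: the L2 distance between Laplacian spectral
#'   densities `rho(w) = K * sum_i gamma / ((w - w_i)^2 + gamma^2)` with
#'   `w_i = sqrt(lambda_i)` over the Laplacian eigenvalues (one zero mode
#'   dropped) and `K` normalizing the density to unit mass on `[0, Inf)`;
#'   the width `gamma` is calibrated numerically per node count so that
#'   `IM(empty graph, complete graph) = 1`;
#' * `HIM = sqrt(H^2 + IM^2) / sqrt(2)`, which lies in `[0, 1]` and is 0
#'   iff the adjacencies coincide.
#'
#' @name him
NULL

.him_env <- new.env(parent = emptyenv())

laplacian_omegas <- function(mat) {
  L <- diag(rowSums(mat)) - mat
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(pmax(ev, 0))
  sqrt(ev[-1])  # drop one zero mode
}

# analytic normalization: integral of a unit lorentzian over [0, Inf)
lorentz_mass <- function(omegas, gamma) {
  sum(pi / 2 + atan(omegas / gamma))
}

spectral_density_fun <- function(omegas, gamma) {
  k <- 1 / lorentz_mass(omegas, gamma)
  function(w) {
    k * colSums(gamma / (outer(omegas, w, "-")^2 + gamma^2))
  }
}

im_grid <- function(omega_max, gamma, n_points = 4000L) {
  seq(0, omega_max + 30 * max(gamma, 1), length.out = n_points)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

im_from_omegas <- function(o1, o2, gamma, n_points = 4000L) {
  grid <- im_grid(max(o1, o2, 1), gamma, n_points)
  r1 <- spectral_density_fun(o1, gamma)(grid)
  r2 <- spectral_density_fun(o2, gamma)(grid)
  sqrt(trapz(grid, (r1 - r2)^2))
}

#' Calibrated Ipsen-Mikhailov width for a node count
#'
#' Solves `IM(empty graph, complete graph) = 1` for the Lorentzian width
#' `gamma` at the given node count; results are cached per `n`.
#'
#' @param n node count (>= 2).
#' @return calibrated `gamma`.
#' @export
ipsen_gamma <- function(n) {
  key <- as.character(n)
  if (!is.null(.him_env[[key]])) return(.him_env[[key]])
  o_empty <- rep(0, n - 1L)
  o_full <- rep(sqrt(n), n - 1L)
  f <- function(g) im_from_omegas(o_empty, o_full, g) - 1
  gamma <- stats::uniroot(f, c(0.01, 10), tol = 1e-10)$root
  .him_env[[key]] <- gamma
  gamma
}

#' Ipsen-Mikhailov spectral distance
#'
#' @param g1,g2 weighted adjacency matrices on the same (ordered) node set.
#' @param gamma Lorentzian width; default [ipsen_gamma()] for the node count.
#' @param n_points integration grid size.
#' @return spectral distance in `[0, 1]` (up to numerical error).
#' @export
im_distance <- function(g1, g2, gamma = NULL, n_points = 4000L) {
  check_same_nodes(g1, g2)
  gamma <- gamma %||% ipsen_gamma(nrow(g1))
  im_from_omegas(laplacian_omegas(g1), laplacian_omegas(g2), gamma, n_points)
}

#' Hamming distance between weighted adjacencies
#'
#' Mean absolute adjacency difference over unordered node pairs; equals the
#' classic edge-difference fraction on binary graphs.
#'
#' @inheritParams im_distance
#' @export
hamming_distance <- function(g1, g2) {
  check_same_nodes(g1, g2)
  ut <- upper.tri(g1)
  mean(abs(g1[ut] - g2[ut]))
}

check_same_nodes <- function(g1, g2) {
  if (!identical(dim(g1), dim(g2)) ||
      !identical(rownames(g1), rownames(g2))) {
    stop2("networks must share the same ordered node set")
  }
  invisible(TRUE)
}

#' @rdname him
#' @inheritParams im_distance
#' @return `him_distance()` returns the combined distance in `[0, 1]`.
#' @export
him_distance <- function(g1, g2, gamma = NULL, n_points = 4000L) {
  h <- hamming_distance(g1, g2)
  im <- im_distance(g1, g2, gamma = gamma, n_points = n_points)
  sqrt(h^2 + im^2) / sqrt(2)
}

#' Pairwise HIM distance matrix for a set of networks
#'
#' Shares one calibrated `gamma`, one integration grid and one spectral
#' density per network across all pairs, which makes all-vs-all comparison
#' of drug mechanism-of-action networks cheap.
#'
#' @param nets named list of weighted adjacency matrices on one node set.
#' @param n_points integration grid size.
#' @return symmetric matrix of HIM distances with zero diagonal.
#' @export
him_matrix <- function(nets, n_points = 4000L) {
  k <- length(nets)
  ids <- names(nets) %||% as.character(seq_len(k))
  for (m in nets[-1]) check_same_nodes(nets[[1]], m)
  n <- nrow(nets[[1]])
  gamma <- ipsen_gamma(n)
  omegas <- lapply(nets, laplacian_omegas)
  grid <- im_grid(max(unlist(omegas), 1), gamma, n_points)
  dens <- vapply(omegas, function(o) spectral_density_fun(o, gamma)(grid),
                 numeric(length(grid)))
  ut_list <- lapply(nets, function(m) m[upper.tri(m)])
  out <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      h <- mean(abs(ut_list[[i]] - ut_list[[j]]))
      im <- sqrt(trapz(grid, (dens[, i] - dens[, j])^2))
      out[i, j] <- out[j, i] <- sqrt(h^2 + im^2) / sqrt(2)
    }
  }
  out
}
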