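#' Default genetic-algorithm configuration
#'
#' Population of 100 chromosomes; 20 offspring per generation, each
#' produced by one-point crossover (probability 0.70) or bit-swap mutation
#' (probability 0.30); bits initialized to 1 with probability 0.30; per-bit
#' swap-trigger probability 0.10; Hall of Fame capacity 10.
#'
#' @param ... overrides for any configuration field.
#' @return named list of GA parameters.
#' @export
ga_config <- function(...) {
  cfg <- list(population_size = 100L, offspring = 20L,
              p_crossover = 0.70, p_mutation = 0.30,
              p_bit_init = 0.30, p_swap = 0.10,
              hof_size = 10L, generations = 2000L,
              coverage = "mean",      # or "sum"
              pair_norm = "size")     # or "pairs"
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop2("unknown GA config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$p_bit_init < 0 || cfg$p_bit_init > 1) stop2("p_bit_init must be in [0, 1]")
  if (cfg$generations < 1L) stop2("generations must be >= 1")
  if (abs(cfg$p_crossover + cfg$p_mutation - 1) > 1e-12) {
    stop2("p_crossover + p_mutation must equal 1")
  }
  cfg
}

# worst-case sentinel assigned to combinations of fewer than 2 drugs;
# any valid objective vector dominates it
sentinel_objectives <- function() rep(-1e9, 5L)

#' Evaluate the five objectives of a drug combination
#'
#' For a combination `x` of `n >= 2` drugs (all maximized):
#' `MOA = sum of pairwise HIM / n`, `SMILES = sum of pairwise Levenshtein /
#' n`, `TARGETS = sum of pairwise mean shortest paths / n` (normalization by
#' the combination size, not the pair count; set `pair_norm = "pairs"` in
#' the config for per-pair averaging), `COVERAGE = mean` (or sum) `of member
#' effect scores`, and `-SIZE = -n`.  Combinations with fewer than two
#' drugs receive a worst-case sentinel vector dominated by every valid one.
#'
#' @param bits 0/1 integer vector over the drug universe.
#' @param feats `drug_feature_tables` from [build_feature_tables()].
#' @param config GA configuration (uses `coverage` and `pair_norm`).
#' @return numeric vector `c(moa, smiles, targets, coverage, neg_size)`.
#' @export
evaluate_combination <- function(bits, feats, config = ga_config()) {
  idx <- which(bits == 1L)
  n <- length(idx)
  if (n < 2L) return(sentinel_objectives())
  denom <- if (config$pair_norm == "pairs") n * (n - 1) / 2 else n
  moa <- sum(feats$him[idx, idx]) / 2 / denom
  smi <- sum(feats$lev[idx, idx]) / 2 / denom
  tgt <- sum(feats$sp[idx, idx]) / 2 / denom
  cov <- if (config$coverage == "sum") sum(feats$es[idx]) else mean(feats$es[idx])
  c(moa, smi, tgt, cov, -n)
}

#' Initialize a population of random chromosomes
#'
#' Bits are i.i.d. Bernoulli(`p_one`).
#'
#' @param n population size.
#' @param length chromosome length (drug universe size).
#' @param p_one probability that a bit starts at 1.
#' @param seed optional RNG seed.
#' @return integer 0/1 matrix, `n` x `length`, one chromosome per row.
#' @export
initialize_population <- function(n = 100L, length, p_one = 0.30, seed = NULL) {
  if (p_one < 0 || p_one > 1) stop2("p_one must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(n * length, 1L, p_one), nrow = n, ncol = length)
}

#' One-point crossover (first child only)
#'
#' The chromosomes are split at `cut` and the left part of `p1` is joined
#' to the right part of `p2`; the complementary second child is discarded.
#'
#' @param p1,p2 parent 0/1 vectors of equal length.
#' @param cut split position, `1 <= cut < length`.
#' @return child chromosome.
#' @export
one_point_crossover <- function(p1, p2, cut) {
  l <- length(p1)
  if (length(p2) != l) stop2("parents must have equal length")
  if (cut < 1L || cut >= l) stop2("cut must satisfy 1 <= cut < length")
  c(p1[seq_len(cut)], p2[(cut + 1L):l])
}

#' Bit-swap mutation
#'
#' Sequential scan: each position fires with probability `p_swap` and, when
#' it fires, exchanges its value with a uniformly chosen other position.
#' Swapping conserves the number of set bits.
#'
#' @param chrom 0/1 vector of length >= 2.
#' @param p_swap per-position trigger probability.
#' @return mutated chromosome, with attribute `n_fired` (number of
#'   positions whose swap event fired).
#' @export
swap_mutation <- function(chrom, p_swap = 0.10) {
  l <- length(chrom)
  if (l < 2L) stop2("chromosome length must be >= 2")
  fires <- which(runif(l) < p_swap)
  for (i in fires) {
    j <- sample.int(l - 1L, 1L)
    if (j >= i) j <- j + 1L
    tmp <- chrom[i]; chrom[i] <- chrom[j]; chrom[j] <- tmp
  }
  attr(chrom, "n_fired") <- length(fires)
  chrom
}

bits_key <- function(bits) paste(bits, collapse = "")

# D[i, j] TRUE iff row i of x dominates row j of y (all objectives maximized)
cross_dominance <- function(x, y) {
  ge <- matrix(TRUE, nrow(x), nrow(y))
  gt <- matrix(FALSE, nrow(x), nrow(y))
  for (k in seq_len(ncol(x))) {
    ge <- ge & outer(x[, k], y[, k], ">=")
    gt <- gt | outer(x[, k], y[, k], ">")
  }
  ge & gt
}

# incrementally merge new evaluated individuals into an unbounded Pareto
# archive; only the newcomers are compared against the current members
archive_update <- function(archive, bits_mat, objs) {
  keys <- apply(bits_mat, 1, bits_key)
  fresh <- !duplicated(keys) & objs[, 5] > -1e8 & !(keys %in% archive$keys)
  if (!any(fresh)) return(archive)
  nb <- bits_mat[fresh, , drop = FALSE]
  no <- objs[fresh, , drop = FALSE]
  nk <- keys[fresh]
  if (length(archive$keys)) {
    ok <- colSums(cross_dominance(archive$objs, no)) == 0L
    nb <- nb[ok, , drop = FALSE]; no <- no[ok, , drop = FALSE]; nk <- nk[ok]
  }
  if (nrow(no) > 1L) {
    nd <- colSums(dominance_matrix(no)) == 0L
    nb <- nb[nd, , drop = FALSE]; no <- no[nd, , drop = FALSE]; nk <- nk[nd]
  }
  if (nrow(no) == 0L) return(archive)
  if (length(archive$keys)) {
    keep <- colSums(cross_dominance(no, archive$objs)) == 0L
    archive$bits <- archive$bits[keep, , drop = FALSE]
    archive$objs <- archive$objs[keep, , drop = FALSE]
    archive$keys <- archive$keys[keep]
  }
  list(bits = rbind(archive$bits, nb),
       objs = rbind(archive$objs, no),
       keys = c(archive$keys, nk))
}

# Hall of Fame: archive truncated to capacity by descending crowding distance
hof_view <- function(archive, capacity) {
  n <- nrow(archive$objs)
  if (n <= capacity) return(archive)
  cd <- crowding_distance(archive$objs)
  keep <- order(-cd, seq_len(n), method = "radix")[seq_len(capacity)]
  keep <- sort(keep)
  list(bits = archive$bits[keep, , drop = FALSE],
       objs = archive$objs[keep, , drop = FALSE])
}

#' Run the multi-objective genetic algorithm
#'
#' Each generation produces `offspring` (default 20) new chromosomes — each
#' by one-point crossover of two randomly chosen parents (probability
#' `p_crossover`) or by bit-swap mutation of one random parent — evaluates
#' them, and selects the best `population_size` (default 100) individuals
#' from the union of parents and offspring with NSGA-II.  A Pareto archive
#' is updated every iteration; the Hall of Fame is the archive truncated to
#' `hof_size` members by crowding distance.
#'
#' @param feats `drug_feature_tables` over the drug universe.
#' @param config GA configuration from [ga_config()].
#' @param seed RNG seed for the whole run.
#' @return object of class `optimizer_state`: `population`, `objectives`,
#'   `generation`, `hof` (bits, objectives, decoded drug combinations),
#'   `archive`, `traces` (long data frame: generation, objective,
#'   min/mean/max over valid individuals), `operator_counts`, `config`,
#'   `seed`.
#' @export
run_optimizer <- function(feats, config = ga_config(), seed = NULL) {
  n_drugs <- length(feats$drug_ids)
  if (n_drugs < 2L) stop2("need at least 2 drugs in the universe")
  if (!is.null(seed)) set.seed(seed)
  np <- config$population_size
  noff <- config$offspring
  objective_names <- c("moa", "smiles", "targets", "coverage", "neg_size")

  pop <- initialize_population(np, n_drugs, config$p_bit_init)
  objs <- t(apply(pop, 1, evaluate_combination, feats = feats, config = config))
  archive <- archive_update(list(bits = NULL, objs = NULL, keys = character()),
                            pop, objs)

  n_cross <- 0L; n_mut <- 0L
  traces <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    child_mat <- matrix(0L, noff, n_drugs)
    for (o in seq_len(noff)) {
      if (runif(1) < config$p_crossover) {
        par <- sample.int(np, 2L)
        cut <- sample.int(n_drugs - 1L, 1L)
        child <- one_point_crossover(pop[par[1L], ], pop[par[2L], ], cut)
        n_cross <- n_cross + 1L
      } else {
        par <- sample.int(np, 1L)
        child <- swap_mutation(pop[par, ], config$p_swap)
        n_mut <- n_mut + 1L
      }
      child_mat[o, ] <- child
    }
    child_objs <- t(apply(child_mat, 1, evaluate_combination,
                          feats = feats, config = config))
    pool <- rbind(pop, child_mat)
    pool_objs <- rbind(objs, child_objs)
    sel <- nsga2_select(pool_objs, np)
    pop <- pool[sel, , drop = FALSE]
    objs <- pool_objs[sel, , drop = FALSE]
    archive <- archive_update(archive, child_mat, child_objs)

    valid <- objs[, 5] > -1e8
    vo <- objs[valid, , drop = FALSE]
    traces[[gen]] <- data.frame(
      generation = gen,
      objective = objective_names,
      min = if (nrow(vo)) apply(vo, 2, min) else NA_real_,
      mean = if (nrow(vo)) colMeans(vo) else NA_real_,
      max = if (nrow(vo)) apply(vo, 2, max) else NA_real_,
      stringsAsFactors = FALSE)
  }
  hof <- hof_view(archive, config$hof_size)
  hof$combinations <- apply(hof$bits, 1, function(b) feats$drug_ids[b == 1L],
                            simplify = FALSE)
  colnames(hof$objs) <- objective_names
  structure(list(population = pop, objectives = objs,
                 generation = config$generations,
                 hof = hof, archive = archive,
                 traces = do.call(rbind, traces),
                 operator_counts = c(crossover = n_cross, mutation = n_mut),
                 config = config, seed = seed),
            class = "optimizer_state")
}

#' @export
print.optimizer_state <- function(x, ...) {
  cat(sprintf("optimizer_state: %d generations, population %d, HoF %d combination(s)\n",
              x$generation, nrow(x$population), nrow(x$hof$bits)))
  for (i in seq_along(x$hof$combinations)) {
    cat(sprintf("  [%d] {%s}\n", i, paste(x$hof$combinations[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Stability analysis across repeated optimizer runs
#'
#' Runs the genetic algorithm `n_runs` times with distinct seeds,
#' aggregates all Hall-of-Fame combinations, and builds the
#' combination-frequency network: a drug-drug edge weighted by the number
#' of Hall-of-Fame solutions (across runs) containing both drugs.  Per-run
#' agreement is summarized by the Jaccard index of the runs' drug-pair
#' sets.
#'
#' @param feats `drug_feature_tables`.
#' @param config GA configuration.
#' @param n_runs number of repeated runs (>= 2).
#' @param seeds integer vector of length `n_runs`; default `seed + 0:(n_runs - 1)`.
#' @param seed base seed used when `seeds` is not given.
#' @return list: `runs` (list of `optimizer_state`), `frequency_edges`
#'   (data frame `drug_a`, `drug_b`, `weight`), `jaccard` (n_runs x n_runs
#'   matrix), `hof_combinations` (data frame run, member, drugs).
#' @export
stability_analysis <- function(feats, config = ga_config(), n_runs = 10L,
                               seeds = NULL, seed = 1L) {
  if (n_runs < 2L) stop2("n_runs must be >= 2")
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  if (length(seeds) != n_runs) stop2("need one seed per run")
  runs <- lapply(seeds, function(s) run_optimizer(feats, config, seed = s))

  combos <- list(); run_of <- integer(0)
  for (r in seq_along(runs)) {
    for (cb in runs[[r]]$hof$combinations) {
      combos[[length(combos) + 1L]] <- cb
      run_of <- c(run_of, r)
    }
  }
  pair_rows <- lapply(combos, function(cb) {
    if (length(cb) < 2L) return(NULL)
    cmb <- utils::combn(sort(cb), 2L)
    data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  freq <- if (is.null(pairs)) {
    data.frame(drug_a = character(), drug_b = character(), weight = integer())
  } else {
    ag <- stats::aggregate(list(weight = rep(1L, nrow(pairs))),
                           by = pairs, FUN = sum)
    ag[order(-ag$weight, ag$drug_a, ag$drug_b), , drop = FALSE]
  }
  rownames(freq) <- NULL

  pair_sets <- lapply(seq_along(runs), function(r) {
    idx <- which(run_of == r)
    unique(unlist(lapply(pair_rows[idx], function(df) {
      if (is.null(df)) character(0) else edge_key(df$drug_a, df$drug_b)
    })))
  })
  jac <- matrix(1, n_runs, n_runs)
  for (i in seq_len(n_runs - 1L)) for (j in (i + 1L):n_runs) {
    u <- length(union(pair_sets[[i]], pair_sets[[j]]))
    jac[i, j] <- jac[j, i] <- if (u == 0L) 1 else
      length(intersect(pair_sets[[i]], pair_sets[[j]])) / u
  }
  hof_df <- data.frame(run = run_of,
                       member = unlist(lapply(table(run_of), seq_len)),
                       drugs = vapply(combos, paste, character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  list(runs = runs, frequency_edges = freq, jaccard = jac,
       hof_combinations = hof_df, seeds = seeds)
}

#' Export a Hall of Fame as JSON and traces / frequency network as TSV
#'
#' @param state an `optimizer_state`.
#' @param path output JSON path.
#' @export
write_hof_json <- function(state, path) {
  members <- lapply(seq_along(state$hof$combinations), function(i) {
    list(bits = paste(state$hof$bits[i, ], collapse = ""),
         drugs = state$hof$combinations[[i]],
         objectives = as.list(state$hof$objs[i, ]))
  })
  jsonlite::write_json(list(seed = state$seed, generations = state$generation,
                            members = members),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
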