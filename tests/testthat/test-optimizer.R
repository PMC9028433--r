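# small synthetic feature tables for GA mechanics tests
toy_feats <- function(k = 8, seed = 71) {
  set.seed(seed)
  ids <- sprintf("d%02d", seq_len(k))
  sym <- function(scale) {
    m <- matrix(runif(k * k) * scale, k, k, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2; diag(m) <- 0; m
  }
  structure(list(drug_ids = ids, him = sym(1), lev = round(sym(40)),
                 sp = sym(10), es = setNames(runif(k, 0.1, 2), ids),
                 targets = setNames(rep(list("x"), k), ids),
                 excluded = data.frame()),
            class = "drug_feature_tables")
}

test_that("objective evaluation follows the size-normalized formulas", {
  f <- toy_feats(4)
  f$him[1, 2] <- f$him[2, 1] <- 0.6
  b <- c(1L, 1L, 0L, 0L)
  o <- evaluate_combination(b, f)
  expect_equal(o[1], 0.6 / 2)
  expect_equal(o[2], f$lev[1, 2] / 2)
  expect_equal(o[3], f$sp[1, 2] / 2)
  expect_equal(o[4], mean(f$es[1:2]))
  expect_equal(o[5], -2)
  # 3-drug combination against hand arithmetic
  b3 <- c(1L, 1L, 1L, 0L)
  o3 <- evaluate_combination(b3, f)
  expect_equal(o3[1], (f$him[1, 2] + f$him[1, 3] + f$him[2, 3]) / 3)
  expect_equal(o3[4], mean(f$es[1:3]))
  expect_equal(o3[5], -3)
  # pair-count normalization via config
  cfg <- ga_config(pair_norm = "pairs")
  expect_equal(evaluate_combination(b3, f, cfg)[1],
               (f$him[1, 2] + f$him[1, 3] + f$him[2, 3]) / 3)
  b4 <- c(1L, 1L, 1L, 1L)
  expect_equal(evaluate_combination(b4, f, cfg)[1],
               sum(f$him[upper.tri(f$him)]) / 6)
  expect_equal(evaluate_combination(b4, f)[1], sum(f$him[upper.tri(f$him)]) / 4)
})

test_that("invalid combinations get a sentinel dominated by any valid vector", {
  f <- toy_feats(4)
  s0 <- evaluate_combination(rep(0L, 4), f)
  s1 <- evaluate_combination(c(1L, 0L, 0L, 0L), f)
  valid <- evaluate_combination(c(1L, 1L, 0L, 0L), f)
  expect_identical(s0, s1)
  expect_true(dominates_oracle(valid, s0))
})

test_that("population initialization is Bernoulli with the configured rate", {
  expect_true(all(initialize_population(20, 10, 0, seed = 1) == 0))
  expect_true(all(initialize_population(20, 10, 1, seed = 1) == 1))
  expect_error(initialize_population(10, 10, 1.2), "p_one")
  pop <- initialize_population(10000, 100, 0.30, seed = 99)
  expect_equal(dim(pop), c(10000, 100))
  expect_equal(mean(pop), 0.30, tolerance = 0.01 / 0.30)
})

test_that("one-point crossover splices left and right parent segments", {
  p1 <- rep(1L, 4); p2 <- rep(0L, 4)
  expect_equal(one_point_crossover(p1, p2, 2), c(1L, 1L, 0L, 0L))
  expect_equal(one_point_crossover(p1, p1, 3), p1)
  expect_error(one_point_crossover(p1, p2, 0), "cut")
  expect_error(one_point_crossover(p1, p2, 4), "cut")
  # enumeration over all cuts bounds the child bit count
  set.seed(72)
  a <- rbinom(12, 1, 0.5); b <- rbinom(12, 1, 0.5)
  counts <- sapply(1:11, function(cut) sum(one_point_crossover(a, b, cut)))
  for (cut in 1:11) {
    manual <- sum(a[1:cut]) + sum(b[(cut + 1):12])
    expect_equal(counts[cut], manual)
  }
})

test_that("bit-swap mutation conserves the number of set bits", {
  set.seed(73)
  chrom <- rbinom(30, 1, 0.3)
  expect_identical(as.integer(swap_mutation(chrom, 0)),
                   as.integer(chrom))
  for (i in 1:50) {
    out <- swap_mutation(chrom, runif(1))
    expect_equal(sum(out), sum(chrom))
  }
  expect_error(swap_mutation(1L), "length")
})

test_that("NSGA-II front assignment equals the brute-force dominance oracle", {
  set.seed(74)
  for (trial in 1:10) {
    n <- sample(10:60, 1)
    objs <- matrix(rnorm(n * 5), n, 5)
    got <- front_of(pareto_fronts(objs), n)
    expect_equal(got, fronts_oracle(objs))
  }
  # duplicated vectors share a front
  objs <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_equal(front_of(pareto_fronts(objs), 3), c(1, 1, 2))
  # single individual
  expect_equal(pareto_fronts(matrix(1:5, 1))[[1]], 1L)
})

test_that("environmental selection fills by front and truncates by crowding", {
  set.seed(75)
  objs <- matrix(rnorm(40 * 3), 40, 3)
  sel <- nsga2_select(objs, 15)
  expect_length(sel, 15)
  fr <- front_of(pareto_fronts(objs), 40)
  # every selected individual is from a front no worse than any unselected one
  expect_true(max(fr[sel]) <= min(fr[setdiff(seq_len(40), sel)]))
  expect_error(nsga2_select(objs, 41), "pool")
  # boundary points of a front get infinite crowding distance
  f1 <- matrix(c(0, 1, 0.5, 3, 1, 2), 3, 2)
  cd <- crowding_distance(f1)
  expect_true(is.infinite(cd[1]) && is.infinite(cd[2]))
})

test_that("the optimizer respects the printed population mechanics", {
  f <- toy_feats(8)
  cfg <- ga_config(generations = 50)
  st <- run_optimizer(f, cfg, seed = 7)
  expect_equal(nrow(st$population), 100)
  expect_equal(sum(st$operator_counts), 50 * 20)
  expect_lte(nrow(st$hof$bits), 10)
  # traces carry one row per generation and objective
  expect_equal(nrow(st$traces), 50 * 5)
  expect_error(run_optimizer(f, ga_config(generations = 0)), "generations")
})

test_that("the Hall of Fame is a mutually non-dominated, valid-size archive head", {
  f <- toy_feats(10, seed = 76)
  st <- run_optimizer(f, ga_config(generations = 80), seed = 11)
  ho <- st$hof$objs
  for (i in seq_len(nrow(ho))) for (j in seq_len(nrow(ho))) {
    if (i != j) expect_false(dominates_oracle(ho[i, ], ho[j, ]))
  }
  # no member of the final population or archive dominates a HoF member
  others <- rbind(st$objectives, st$archive$objs)
  for (i in seq_len(nrow(ho))) {
    for (j in seq_len(nrow(others))) {
      expect_false(dominates_oracle(others[j, ], ho[i, ]))
    }
  }
  # sentinel safety: every HoF combination has at least two drugs
  expect_true(all(rowSums(st$hof$bits) >= 2))
  expect_true(all(lengths(st$hof$combinations) >= 2))
})

test_that("runs are bitwise reproducible under a fixed seed", {
  f <- toy_feats(8)
  cfg <- ga_config(generations = 40)
  a <- run_optimizer(f, cfg, seed = 123)
  b <- run_optimizer(f, cfg, seed = 123)
  expect_identical(a$hof, b$hof)
  expect_identical(a$traces, b$traces)
  expect_identical(a$population, b$population)
  c <- run_optimizer(f, cfg, seed = 124)
  expect_false(identical(a$population, c$population))
})

test_that("stability analysis counts combination pairs and reports agreement", {
  f <- toy_feats(8)
  cfg <- ga_config(generations = 30)
  stab <- stability_analysis(f, cfg, n_runs = 3, seeds = c(5, 5, 5))
  # identical seeds: identical HoFs and Jaccard 1 everywhere
  expect_true(all(stab$jaccard == 1))
  expect_identical(stab$runs[[1]]$hof, stab$runs[[2]]$hof)
  # frequency network equals brute-force counting over concatenated HoFs
  combos <- unlist(lapply(stab$runs, function(r) r$hof$combinations),
                   recursive = FALSE)
  for (r in seq_len(nrow(stab$frequency_edges))) {
    e <- stab$frequency_edges[r, ]
    manual <- sum(vapply(combos, function(cb)
      all(c(e$drug_a, e$drug_b) %in% cb), logical(1)))
    expect_equal(e$weight, manual)
  }
  expect_error(stability_analysis(f, cfg, n_runs = 1), "n_runs")
  stab2 <- stability_analysis(f, cfg, n_runs = 2, seed = 9)
  expect_length(stab2$runs, 2)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(ga_config(nonsense = 1), "unknown")
  expect_error(ga_config(p_bit_init = 2), "p_bit_init")
  expect_error(ga_config(p_crossover = 0.5, p_mutation = 0.3), "equal 1")
})
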