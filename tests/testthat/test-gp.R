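cfg <- gp_config()

collect_terminals <- function(tree) {
  if (is.null(tree$kids)) return(list(tree))
  do.call(c, lapply(tree$kids, collect_terminals))
}

test_that("random trees respect the depth bounds and the terminal set", {
  set.seed(1)
  trees <- replicate(10000, random_tree(cfg), simplify = FALSE)
  depths <- vapply(trees, tree_depth, integer(1))
  expect_true(all(depths >= 2 & depths <= 6))
  ercs <- unlist(lapply(trees[1:2000], function(t) {
    vals <- vapply(collect_terminals(t), function(nd) {
      if (identical(nd$op, "erc")) nd$value else NA_integer_
    }, integer(1))
    vals[!is.na(vals)]
  }))
  expect_true(all(ercs == round(ercs)))
  expect_true(all(ercs >= -5 & ercs <= 5))
  # same RNG state gives the identical tree
  set.seed(99); t1 <- random_tree(cfg)
  set.seed(99); t2 <- random_tree(cfg)
  expect_identical(t1, t2)
})

test_that("tree evaluation matches the arithmetic it encodes", {
  quad <- sexp_to_tree(list("add", list("multiply", "x", "x"),
                            list("negate", list("multiply", "x", 5L))))
  expect_equal(evaluate_tree(quad, 2), -6)       # 4 - 10
  expect_equal(evaluate_tree(quad, c(0, 1, 3)), c(0, -4, -6))
  ident <- sexp_to_tree(list("add", "x", 0L))
  xs <- runif(20, -3, 3)
  expect_identical(evaluate_tree(ident, xs), xs + 0)
  # protected division
  expect_equal(evaluate_tree(sexp_to_tree(list("divide", 1L, 0L)), 0), 1)
  expect_equal(evaluate_tree(sexp_to_tree(list("divide", 4L, 2L)), 0), 2)
  expect_error(evaluate_tree(list(op = "bogus"), 1),
               class = "dot_structure_error")
})

test_that("evaluation agrees with an independent reference evaluator", {
  set.seed(7)
  for (i in 1:2000) {
    tr <- random_tree(cfg)
    x <- runif(5, -10, 10)
    a <- evaluate_tree(tr, x)
    b <- reference_eval(tr, x)
    ok <- is.finite(a) & is.finite(b)
    expect_identical(is.finite(a), is.finite(b))
    if (any(ok)) {
      expect_lt(max(abs(a[ok] - b[ok]) / pmax(abs(b[ok]), 1e-300)), 1e-12)
    }
  }
})

test_that("serialization to prefix s-expressions is lossless", {
  set.seed(12)
  for (i in 1:200) {
    tr <- random_tree(cfg)
    json <- jsonlite::toJSON(tree_to_sexp(tr), auto_unbox = TRUE)
    back <- sexp_to_tree(jsonlite::fromJSON(json, simplifyVector = FALSE))
    expect_identical(back, tr)
  }
  quad <- list("add", list("multiply", "x", "x"),
               list("negate", list("multiply", "x", 5L)))
  expect_equal(as.character(jsonlite::toJSON(tree_to_sexp(sexp_to_tree(quad)),
                                             auto_unbox = TRUE)),
               '["add",["multiply","x","x"],["negate",["multiply","x",5]]]')
})

test_that("fitness is RMSE on a subsample with an Inf sentinel for failures", {
  ident <- sexp_to_tree(list("add", "x", 0L))
  expect_error(gp_fitness(ident, numeric(0), numeric(0)),
               class = "dot_evaluation_error")
  set.seed(3)
  preds <- runif(100)
  expect_equal(gp_fitness(ident, preds, preds, subsample_fraction = 1), 0)
  zero <- sexp_to_tree(list("multiply", "x", 0L))
  expect_equal(gp_fitness(zero, preds, rep(1, 100), subsample_fraction = 1), 1)
  # overflowing tree hits the sentinel
  big <- sexp_to_tree(list("multiply", "x", "x"))
  expect_equal(gp_fitness(big, rep(1e300, 10), rep(0, 10),
                          subsample_fraction = 1), Inf)
})

test_that("tournament selection returns the fittest of its draws", {
  pop <- lapply(1:4, function(i) sexp_to_tree(list("add", "x", as.integer(i))))
  fits <- c(3, 1, 4, 2)
  set.seed(5)
  expect_identical(tournament_select(pop[1], fits[1], k = 3), pop[[1]])
  # with k = population size over many seeded draws, the global best
  # dominates and no winner is ever beaten by every drawn rival
  set.seed(6)
  wins <- replicate(1000, {
    which(vapply(pop, identical, logical(1),
                 tournament_select(pop, fits, k = 4)))
  })
  expect_gt(mean(wins == 2), 0.6)  # P(best drawn at least once) = 1-(3/4)^4
  # selection pressure: winners are fitter than the population average
  set.seed(8)
  popf <- runif(50)
  winf <- replicate(1000, {
    idx <- sample.int(50, 4, replace = TRUE)
    min(popf[idx])
  })
  expect_lt(mean(winf), mean(popf))
  expect_error(tournament_select(list(), numeric(0)),
               class = "dot_selection_error")
})

test_that("crossover and mutation keep every offspring inside the search space", {
  set.seed(10)
  for (i in 1:2500) {
    a <- random_tree(cfg)
    b <- random_tree(cfg)
    kids <- gp_crossover(a, b, cfg)
    for (k in kids) {
      dk <- tree_depth(k)
      expect_true(dk >= 2 && dk <= 6)
      expect_identical(sexp_to_tree(tree_to_sexp(k)), k)
    }
    m <- gp_mutate(a, cfg)
    dm <- tree_depth(m)
    expect_true(dm >= 2 && dm <= 6)
    # mutation is a single-point alteration: grafting the parent's subtree
    # back at the common ancestor of all differences restores the parent
    diffs <- tree_diff_paths(a, m)
    if (length(diffs) > 0) {
      lcp <- diffs[[1]]
      for (p in diffs) {
        keep <- 0L
        while (keep < length(lcp) && keep < length(p) &&
               all(lcp[seq_len(keep + 1)] == p[seq_len(keep + 1)])) {
          keep <- keep + 1L
        }
        lcp <- lcp[seq_len(keep)]
      }
      reverted <- dotinverse:::tree_set(m, lcp, dotinverse:::tree_get(a, lcp))
      expect_identical(reverted, a)
    }
  }
  # identical parents exchanging the same node reproduce the parents
  a <- sexp_to_tree(list("add", "x", 1L))
  set.seed(2)
  kids <- gp_crossover(a, a, cfg)
  expect_true(identical(kids[[1]], a) || tree_depth(kids[[1]]) <= 6)
})

test_that("ERC mutation stays on integers in [-5, 5]", {
  erc_tree <- sexp_to_tree(list("add", "x", 3L))
  set.seed(4)
  hit <- 0
  for (i in 1:200) {
    m <- gp_mutate(erc_tree, cfg)
    vals <- vapply(collect_terminals(m), function(nd) {
      if (identical(nd$op, "erc")) nd$value else NA_integer_
    }, integer(1))
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= -5 & vals <= 5))
    expect_true(all(vals == round(vals)))
    if (length(tree_diff_paths(erc_tree, m)) == 1 &&
        identical(tree_diff_paths(erc_tree, m)[[1]], 2L) &&
        identical(m$kids[[2]]$op, "erc")) {
      hit <- hit + 1
      expect_false(identical(m$kids[[2]]$value, 3L))
    }
  }
  expect_gt(hit, 10)  # the ERC perturbation branch is exercised
})

test_that("evolution recovers identity and constant-offset corrections", {
  set.seed(1)
  preds <- runif(200, 0, 1)
  small <- gp_config(population_size = 300L, generations = 20L, n_runs = 2L,
                     seed = 5L)
  res_id <- evolve(preds, preds, small)
  expect_lt(res_id$best_fitness, 1e-3)
  res_off <- evolve(preds, preds + 3, small)
  expect_lt(res_off$best_fitness, 1e-3)
  # running best never increases within a run
  for (r in seq_len(ncol(res_off$fitness_history))) {
    expect_true(all(diff(res_off$fitness_history[, r]) <= 0))
  }
  # the evolved offset correction transfers to held-out data
  new_preds <- runif(100)
  corrected <- evaluate_tree(res_off$best_tree, new_preds)
  expect_lt(rmse(corrected, new_preds + 3), rmse(new_preds, new_preds + 3))
})

test_that("refinement applies one tree per label and preserves shape", {
  ident <- list(best_tree = sexp_to_tree(list("add", "x", 0L)))
  results <- rep(list(ident), 5)
  preds <- matrix(runif(50), 10, 5)
  expect_equal(refine_predictions(results, preds), preds,
               ignore_attr = TRUE)
  offset <- list(best_tree = sexp_to_tree(list("add", "x", 1L)))
  res2 <- c(rep(list(ident), 4), list(offset))
  out <- refine_predictions(res2, preds)
  expect_true(all(out[, 5] == 1))  # clipped at the normalized ceiling
  expect_equal(dim(out), c(10L, 5L))
  expect_error(refine_predictions(results[1:3], preds),
               class = "dot_application_error")
})

test_that("invalid GP configurations are rejected", {
  expect_error(gp_config(p_reproduction = 0.7, p_crossover = 0.5),
               class = "dot_config_error")
  expect_error(gp_config(population_size = 2, tournament_size = 4),
               class = "dot_config_error")
})
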