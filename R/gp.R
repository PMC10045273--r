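## Koza-style tree GP for per-label symbolic-regression corrections.
##
## An individual is an R -> R arithmetic program over one input coordinate:
## internal nodes are add / subtract / multiply / protected divide / negate,
## leaves are the input variable `x` or integer ephemeral random constants
## (ERCs) in [-5, 5]. Tree depth (levels, a lone terminal counting as 1) is
## kept in [2, 6] at creation and after every genetic operation.

gp_binary_ops <- c("add", "subtract", "multiply", "divide")
gp_unary_ops <- "negate"
gp_erc_range <- -5:5

#' GP configuration
#'
#' Defaults are the desk-scale search budget (population 500, 30 generations,
#' 3 independent runs); the reference-scale budget uses populations of
#' 10,000-15,000 and 100-250 generations over 30 runs. Operator
#' probabilities (reproduction 0.35, crossover 0.5, mutation 0.15 including
#' ERC perturbation), tournament size 4, depth bounds `[2, 6]` and the 10%
#' fitness subsample are the reference settings.
#'
#' @param population_size individuals per generation.
#' @param generations generations per run.
#' @param p_reproduction,p_crossover,p_mutation operator probabilities
#'   (must sum to at most 1; one operator is chosen exclusively per
#'   offspring event).
#' @param tournament_size tournament size for parent selection.
#' @param depth_range inclusive tree-depth bounds.
#' @param fitness_subsample_fraction fraction of the training set drawn
#'   (afresh each generation) for fitness evaluation.
#' @param n_runs independent evolutionary runs; the best individual across
#'   runs is returned.
#' @param seed master seed for the run.
#' @return an object of class `gp_config`.
#' @export
gp_config <- function(population_size = 500L, generations = 30L,
                      p_reproduction = 0.35, p_crossover = 0.5,
                      p_mutation = 0.15, tournament_size = 4L,
                      depth_range = c(2L, 6L),
                      fitness_subsample_fraction = 0.1,
                      n_runs = 3L, seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              p_reproduction = p_reproduction, p_crossover = p_crossover,
              p_mutation = p_mutation,
              tournament_size = as.integer(tournament_size),
              depth_range = as.integer(depth_range),
              fitness_subsample_fraction = fitness_subsample_fraction,
              n_runs = as.integer(n_runs), seed = as.integer(seed))
  if (p_reproduction < 0 || p_crossover < 0 || p_mutation < 0 ||
      p_reproduction + p_crossover + p_mutation > 1 + 1e-12) {
    stop_dot("operator probabilities must be non-negative and sum to <= 1",
             class = "dot_config_error")
  }
  if (cfg$population_size < cfg$tournament_size) {
    stop_dot("population_size must be >= tournament_size",
             class = "dot_config_error")
  }
  if (length(cfg$depth_range) != 2L || cfg$depth_range[1] < 1L ||
      diff(cfg$depth_range) < 0) {
    stop_dot("invalid depth_range", class = "dot_config_error")
  }
  class(cfg) <- "gp_config"
  cfg
}

gp_terminal <- function() {
  if (stats::runif(1) < 0.5) {
    list(op = "x")
  } else {
    list(op = "erc", value = sample(gp_erc_range, 1L))
  }
}

gp_function_node <- function(children_gen) {
  op <- sample(c(gp_binary_ops, gp_unary_ops), 1L)
  arity <- if (op %in% gp_unary_ops) 1L else 2L
  list(op = op, kids = lapply(seq_len(arity), function(i) children_gen()))
}

#' Depth of an expression tree (a lone terminal has depth 1)
#' @param tree a GP expression tree.
#' @return integer depth.
#' @export
tree_depth <- function(tree) {
  if (is.null(tree$kids)) return(1L)
  1L + max(vapply(tree$kids, tree_depth, integer(1)))
}

#' Generate a random GP expression tree
#'
#' Ramped half-and-half initialization: a target depth is drawn uniformly
#' from `depth_range` and the tree is built either "full" (all branches reach
#' the target depth) or "grow" (branches may terminate early, never above
#' the target), each with probability 1/2. Uses the current RNG state.
#'
#' @param config a `gp_config` (only `depth_range` is used).
#' @return an expression tree (nested list).
#' @export
random_tree <- function(config = gp_config()) {
  dr <- config$depth_range
  target <- sample(seq(dr[1], dr[2]), 1L)
  full <- stats::runif(1) < 0.5
  gen <- function(depth_left) {
    if (depth_left <= 1L) return(gp_terminal())
    if (!full && depth_left < target && stats::runif(1) < 0.3) {
      return(gp_terminal())
    }
    gp_function_node(function() gen(depth_left - 1L))
  }
  # root is always a function node so depth >= 2
  gp_function_node(function() gen(target - 1L))
}

#' Evaluate a GP expression tree
#'
#' Recursive, vectorized evaluation. Division is protected: whenever
#' `|denominator| < 1e-6` the division returns 1. Non-finite results (from
#' overflow) are returned as-is; [gp_fitness()] maps them to the `+Inf`
#' sentinel.
#'
#' @param tree an expression tree.
#' @param x numeric input vector.
#' @return numeric vector of the same length as `x`.
#' @examples
#' # x^2 + (-5 x) at x = 2 is -6
#' t <- sexp_to_tree(list("add", list("multiply", "x", "x"),
#'                        list("negate", list("multiply", "x", 5L))))
#' evaluate_tree(t, 2)
#' @export
evaluate_tree <- function(tree, x) {
  op <- tree$op
  if (is.null(op)) stop_dot("malformed tree node", class = "dot_structure_error")
  switch(op,
    x = x,
    erc = rep(as.numeric(tree$value), length(x)),
    add = evaluate_tree(tree$kids[[1]], x) + evaluate_tree(tree$kids[[2]], x),
    subtract = evaluate_tree(tree$kids[[1]], x) -
      evaluate_tree(tree$kids[[2]], x),
    multiply = evaluate_tree(tree$kids[[1]], x) *
      evaluate_tree(tree$kids[[2]], x),
    divide = {
      num <- evaluate_tree(tree$kids[[1]], x)
      den <- evaluate_tree(tree$kids[[2]], x)
      ifelse(abs(den) < 1e-6, 1, num / den)
    },
    negate = -evaluate_tree(tree$kids[[1]], x),
    stop_dot("unknown node op '%s'", op, class = "dot_structure_error")
  )
}

#' Serialize a tree to a prefix s-expression
#'
#' The s-expression form is a nested list such as
#' `list("add", list("multiply", "x", "x"), list("negate", list("multiply",
#' "x", 5L)))`, which `jsonlite` renders as
#' `["add",["multiply","x","x"],["negate",["multiply","x",5]]]`.
#'
#' @param tree an expression tree.
#' @return nested list / atomic s-expression.
#' @export
tree_to_sexp <- function(tree) {
  switch(tree$op,
    x = "x",
    erc = as.integer(tree$value),
    c(list(tree$op), lapply(tree$kids, tree_to_sexp))
  )
}

#' Parse a prefix s-expression into a tree
#' @param sexp nested list / atomic s-expression (see [tree_to_sexp()]).
#' @return an expression tree.
#' @export
sexp_to_tree <- function(sexp) {
  if (!is.list(sexp)) {
    if (identical(sexp, "x")) return(list(op = "x"))
    if (is.numeric(sexp)) return(list(op = "erc", value = as.integer(sexp)))
    stop_dot("unknown terminal in s-expression", class = "dot_structure_error")
  }
  op <- sexp[[1]]
  if (!op %in% c(gp_binary_ops, gp_unary_ops)) {
    stop_dot("unknown operator '%s' in s-expression", op,
             class = "dot_structure_error")
  }
  list(op = op, kids = lapply(sexp[-1], sexp_to_tree))
}

# enumerate node paths (root = integer(0); child i of path p = c(p, i))
tree_paths <- function(tree, prefix = integer(0)) {
  out <- list(prefix)
  if (!is.null(tree$kids)) {
    for (i in seq_along(tree$kids)) {
      out <- c(out, tree_paths(tree$kids[[i]], c(prefix, i)))
    }
  }
  out
}

tree_get <- function(tree, path) {
  for (i in path) tree <- tree$kids[[i]]
  tree
}

tree_set <- function(tree, path, sub) {
  if (length(path) == 0L) return(sub)
  tree$kids[[path[1]]] <- tree_set(tree$kids[[path[1]]], path[-1], sub)
  tree
}

#' RMSE fitness of a correction tree on a random data subsample
#'
#' Draws `subsample_fraction` of the aligned (prediction, truth) pairs with
#' the current RNG, applies the tree to the predictions and returns the RMSE
#' against the truths. Any non-finite tree output yields the `+Inf` sentinel
#' (worst possible fitness).
#'
#' @param tree an expression tree.
#' @param predictions,truths aligned numeric vectors.
#' @param subsample_fraction fraction in `(0, 1]`.
#' @return scalar RMSE (lower is better), or `Inf`.
#' @export
gp_fitness <- function(tree, predictions, truths, subsample_fraction = 0.1) {
  n <- length(predictions)
  stopifnot(length(truths) == n)
  m <- max(1L, round(n * subsample_fraction))
  if (n < 1L || m < 1L) {
    stop_dot("empty fitness subsample", class = "dot_evaluation_error")
  }
  idx <- if (m == n) seq_len(n) else sample.int(n, m)
  out <- evaluate_tree(tree, predictions[idx])
  if (any(!is.finite(out))) return(Inf)
  sqrt(mean((out - truths[idx])^2))
}

#' Tournament selection
#'
#' Draws `k` individuals uniformly with replacement and returns the one with
#' the lowest fitness; ties go to the earliest draw.
#'
#' @param population list of individuals.
#' @param fitnesses numeric vector aligned with `population`.
#' @param k tournament size.
#' @return the selected individual.
#' @export
tournament_select <- function(population, fitnesses, k = 4L) {
  if (length(population) == 0L) {
    stop_dot("empty population", class = "dot_selection_error")
  }
  population[[tournament_idx(length(population), fitnesses, k)]]
}

tournament_idx <- function(n, fitnesses, k) {
  idx <- sample.int(n, k, replace = TRUE)
  idx[which.min(fitnesses[idx])]
}

#' Subtree crossover
#'
#' Exchanges subtrees at uniformly chosen nodes of the two parents. Children
#' violating the depth bounds are rejected and re-drawn up to `max_retries`
#' times, after which clones of the parents are returned.
#'
#' @param parent_a,parent_b expression trees.
#' @param config a `gp_config` (depth bounds).
#' @param max_retries bounded retries before falling back to clones.
#' @return list of two children.
#' @export
gp_crossover <- function(parent_a, parent_b, config = gp_config(),
                         max_retries = 10L) {
  dr <- config$depth_range
  for (i in seq_len(max_retries)) {
    pa <- tree_paths(parent_a)
    pb <- tree_paths(parent_b)
    path_a <- pa[[sample.int(length(pa), 1L)]]
    path_b <- pb[[sample.int(length(pb), 1L)]]
    sub_a <- tree_get(parent_a, path_a)
    sub_b <- tree_get(parent_b, path_b)
    child_a <- tree_set(parent_a, path_a, sub_b)
    child_b <- tree_set(parent_b, path_b, sub_a)
    da <- tree_depth(child_a)
    db <- tree_depth(child_b)
    if (da >= dr[1] && da <= dr[2] && db >= dr[1] && db <= dr[2]) {
      return(list(child_a, child_b))
    }
  }
  list(parent_a, parent_b)
}

#' Subtree / ERC mutation
#'
#' Picks a node uniformly. An ERC terminal is perturbed to a different
#' integer in `[-5, 5]`; any other node is replaced by a fresh random
#' subtree capped so the whole tree stays within the depth bounds.
#'
#' @param parent an expression tree.
#' @param config a `gp_config`.
#' @return the mutated tree.
#' @export
gp_mutate <- function(parent, config = gp_config()) {
  dr <- config$depth_range
  paths <- tree_paths(parent)
  path <- paths[[sample.int(length(paths), 1L)]]
  node <- tree_get(parent, path)
  if (identical(node$op, "erc")) {
    node$value <- sample(setdiff(gp_erc_range, node$value), 1L)
    return(tree_set(parent, path, node))
  }
  node_level <- length(path) + 1L
  max_sub_depth <- dr[2] - node_level + 1L
  if (length(path) == 0L) {
    # replacing the root: draw a whole fresh tree within bounds
    return(random_tree(config))
  }
  target <- sample.int(max(max_sub_depth, 1L), 1L)
  gen <- function(depth_left) {
    if (depth_left <= 1L) return(gp_terminal())
    if (stats::runif(1) < 0.3) return(gp_terminal())
    gp_function_node(function() gen(depth_left - 1L))
  }
  tree_set(parent, path, gen(target))
}

#' Evolve a per-label correction program
#'
#' Runs `n_runs` independent generational GP searches for an R -> R
#' correction mapping the stage-one predictions of one label toward the true
#' labels. Each generation: a fresh 10% fitness subsample is drawn, all
#' individuals are scored by RMSE, the generation champion is carried over
#' unchanged (elitism), and the rest of the next population is produced by
#' exclusive choice among reproduction / crossover / mutation with the
#' configured probabilities, parents selected by size-4 tournaments.
#' Generation champions are re-scored on the full training vector and the
#' best across all generations and runs is returned.
#'
#' @param predictions stage-one predictions for one label
#'   (normalized scale), training split.
#' @param truths true normalized labels, aligned with `predictions`.
#' @param config a `gp_config`.
#' @return an object of class `gp_result`: `best_tree`, `best_fitness`
#'   (full-training RMSE), `fitness_history` (running-minimum subsample RMSE
#'   per generation, one column per run), `n_failures` (count of `+Inf`
#'   fitness sentinels observed).
#' @export
evolve <- function(predictions, truths, config = gp_config()) {
  stopifnot(inherits(config, "gp_config"))
  n <- length(predictions)
  if (n < 1L) stop_dot("empty training split", class = "dot_evaluation_error")
  run_seeds <- derive_seeds(config$seed, config$n_runs)
  best_tree <- NULL
  best_full <- Inf
  history <- matrix(NA_real_, config$generations, config$n_runs)
  n_failures <- 0L
  for (run in seq_len(config$n_runs)) {
    res <- with_seed(run_seeds[run], {
      pop <- lapply(seq_len(config$population_size),
                    function(i) random_tree(config))
      champs <- vector("list", config$generations)
      champ_fit <- numeric(config$generations)
      fails <- 0L
      for (gen in seq_len(config$generations)) {
        m <- max(1L, round(n * config$fitness_subsample_fraction))
        idx <- if (m >= n) seq_len(n) else sample.int(n, m)
        ps <- predictions[idx]
        ts <- truths[idx]
        fits <- vapply(pop, function(tr) {
          out <- evaluate_tree(tr, ps)
          if (any(!is.finite(out))) return(Inf)
          sqrt(mean((out - ts)^2))
        }, numeric(1))
        fails <- fails + sum(is.infinite(fits))
        champ <- which.min(fits)
        champs[[gen]] <- pop[[champ]]
        champ_fit[gen] <- fits[champ]
        if (gen == config$generations) break
        nxt <- list(pop[[champ]])  # elitism
        while (length(nxt) < config$population_size) {
          u <- stats::runif(1)
          if (u < config$p_reproduction) {
            nxt[[length(nxt) + 1L]] <-
              pop[[tournament_idx(length(pop), fits, config$tournament_size)]]
          } else if (u < config$p_reproduction + config$p_crossover) {
            pa <- pop[[tournament_idx(length(pop), fits, config$tournament_size)]]
            pb <- pop[[tournament_idx(length(pop), fits, config$tournament_size)]]
            kids <- gp_crossover(pa, pb, config)
            nxt[[length(nxt) + 1L]] <- kids[[1]]
            if (length(nxt) < config$population_size) {
              nxt[[length(nxt) + 1L]] <- kids[[2]]
            }
          } else {
            pa <- pop[[tournament_idx(length(pop), fits, config$tournament_size)]]
            nxt[[length(nxt) + 1L]] <- gp_mutate(pa, config)
          }
        }
        pop <- nxt
      }
      # full-training re-score of the generation champions
      full <- vapply(champs, function(tr) {
        out <- evaluate_tree(tr, predictions)
        if (any(!is.finite(out))) return(Inf)
        sqrt(mean((out - truths)^2))
      }, numeric(1))
      list(champ_fit = champ_fit, best = champs[[which.min(full)]],
           best_full = min(full), fails = fails)
    })
    history[, run] <- cummin(res$champ_fit)
    n_failures <- n_failures + res$fails
    if (res$best_full < best_full) {
      best_full <- res$best_full
      best_tree <- res$best
    }
  }
  structure(
    list(best_tree = best_tree, best_fitness = best_full,
         fitness_history = history, n_failures = n_failures,
         config = config),
    class = "gp_result"
  )
}

#' @export
print.gp_result <- function(x, ...) {
  cat(sprintf("<gp_result> best full-training RMSE %.5g over %d run(s); tree: %s\n",
              x$best_fitness, ncol(x$fitness_history),
              jsonlite::toJSON(tree_to_sexp(x$best_tree), auto_unbox = TRUE)))
  invisible(x)
}

#' Evolve correction programs for all five labels
#'
#' @param predictions `n x 5` stage-one predictions (normalized).
#' @param truths `n x 5` true normalized labels.
#' @param config a `gp_config`; each label uses a seed derived from
#'   `config$seed`.
#' @return named list of five `gp_result` objects (x, y, z, mu_a, radius).
#' @export
evolve_corrections <- function(predictions, truths, config = gp_config()) {
  label_seeds <- derive_seeds(config$seed + 1L, 5L)
  out <- vector("list", 5L)
  names(out) <- label_names
  for (k in seq_len(5L)) {
    cfg <- config
    cfg$seed <- label_seeds[k]
    out[[k]] <- evolve(predictions[, k], truths[, k], cfg)
  }
  out
}

#' Apply evolved corrections to stage-one predictions
#'
#' @param results list of five `gp_result` objects (or anything with a
#'   `best_tree` field), in label order x, y, z, mu_a, radius.
#' @param predictions `n x 5` normalized stage-one predictions.
#' @return `n x 5` corrected predictions, clipped to `[0, 1]`.
#' @export
refine_predictions <- function(results, predictions) {
  predictions <- rbind(predictions)
  if (length(results) != ncol(predictions)) {
    stop_dot("need one evolved tree per label", class = "dot_application_error")
  }
  out <- predictions
  for (k in seq_along(results)) {
    tree <- results[[k]]$best_tree %||% results[[k]]
    if (is.null(tree$op) && is.null(tree$kids)) {
      stop_dot("missing tree for label %d", k, class = "dot_application_error")
    }
    out[, k] <- evaluate_tree(tree, predictions[, k])
  }
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- colnames(predictions)
  out
}
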