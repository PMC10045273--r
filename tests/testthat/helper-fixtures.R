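# shared fixtures, built in code

tiny_phantom <- function(heterogeneity = 0) {
  make_slab_phantom(heterogeneity_amplitude = heterogeneity, seed = 11L)
}

# small optode grids keep forward simulations cheap in unit tests
tiny_layout <- function(phantom, n_sources = 12L, n_detectors = 12L) {
  make_layout(phantom, n_sources, n_detectors, margin = 15)
}

tiny_config <- function(seed = 1L) {
  cfg <- default_config("desk", seed = seed)
  cfg$dataset$n_samples <- 120L
  cfg$dataset$n_nodes <- 200L
  cfg$layout$n_sources <- 12L
  cfg$layout$n_detectors <- 12L
  cfg$gp$population_size <- 120L
  cfg$gp$generations <- 8L
  cfg$gp$n_runs <- 1L
  cfg$eval$seeds <- seed
  cfg
}

# independent reference evaluator for GP trees: compiles the s-expression
# into an R expression string and evaluates it with base arithmetic
reference_eval <- function(tree, x) {
  to_str <- function(s) {
    if (!is.list(s)) {
      if (identical(s, "x")) return("x")
      return(sprintf("(%s)", format(s)))
    }
    op <- s[[1]]
    kids <- vapply(s[-1], to_str, character(1))
    switch(op,
      add = sprintf("(%s + %s)", kids[1], kids[2]),
      subtract = sprintf("(%s - %s)", kids[1], kids[2]),
      multiply = sprintf("(%s * %s)", kids[1], kids[2]),
      divide = sprintf("pdiv(%s, %s)", kids[1], kids[2]),
      negate = sprintf("(-%s)", kids[1]))
  }
  pdiv <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    ifelse(abs(b) < 1e-6, 1, a / b)
  }
  out <- eval(parse(text = to_str(tree_to_sexp(tree))),
              list(x = x, pdiv = pdiv))
  rep_len(out, length(x))
}

# maximal differing subtrees between two trees (paths)
tree_diff_paths <- function(a, b, prefix = integer(0)) {
  same_node <- identical(a$op, b$op) &&
    identical(a$value %||% NULL, b$value %||% NULL) &&
    length(a$kids) == length(b$kids)
  if (!same_node) return(list(prefix))
  out <- list()
  for (i in seq_along(a$kids)) {
    out <- c(out, tree_diff_paths(a$kids[[i]], b$kids[[i]], c(prefix, i)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
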