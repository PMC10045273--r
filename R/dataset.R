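label_names <- c("x", "y", "z", "mu_a", "radius")

# full-precision text serialization of a numeric matrix
write_matrix_csv <- function(m, path) {
  header <- if (is.null(colnames(m))) {
    paste0("V", seq_len(ncol(m)), collapse = ",")
  } else {
    paste(colnames(m), collapse = ",")
  }
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, rows), path)
}

#' Physical normalization bounds for the five tumor labels
#'
#' Bounds are the physical ranges, not data extremes, so normalization is
#' deterministic and dataset-independent: slab extents for x, y, z; the
#' configured contrast range times the background absorption for `mu_a`;
#' `[2, 15]` mm for the radius.
#'
#' @param phantom a `slab_phantom`.
#' @param contrast_range tumor/background absorption multiplier range.
#' @param radius_range radius range, mm.
#' @return a `2 x 5` matrix with rows `min`, `max` and the label columns
#'   `x, y, z, mu_a, radius`.
#' @export
label_bounds <- function(phantom, contrast_range = c(2, 4),
                         radius_range = c(2, 15)) {
  stopifnot(inherits(phantom, "slab_phantom"))
  b <- cbind(
    x = c(0, phantom$size_x),
    y = c(0, phantom$size_y),
    z = c(0, phantom$size_z),
    mu_a = phantom$background$mu_a * contrast_range,
    radius = radius_range
  )
  rownames(b) <- c("min", "max")
  b
}

#' Min-max normalize labels to [0, 1]
#'
#' @param labels numeric matrix `n x 5` (columns `x, y, z, mu_a, radius`) in
#'   physical units.
#' @param bounds a `2 x 5` bounds matrix from [label_bounds()].
#' @return normalized matrix with the bounds attached as attribute `"bounds"`.
#' @seealso [denormalize_labels()]
#' @export
normalize_labels <- function(labels, bounds) {
  labels <- rbind(labels)
  stopifnot(ncol(labels) == ncol(bounds))
  rng <- bounds["max", ] - bounds["min", ]
  if (any(!is.finite(bounds)) || any(rng <= 0)) {
    stop_dot("normalization bounds must be finite with max > min",
             class = "dot_normalization_error")
  }
  out <- sweep(sweep(labels, 2, bounds["min", ]), 2, rng, "/")
  colnames(out) <- colnames(bounds)
  attr(out, "bounds") <- bounds
  out
}

#' Invert min-max label normalization
#'
#' @param labels normalized matrix (from [normalize_labels()]).
#' @param bounds bounds matrix; defaults to the attribute stored on `labels`.
#' @return matrix in physical units.
#' @export
denormalize_labels <- function(labels, bounds = attr(labels, "bounds")) {
  force(bounds)
  labels <- rbind(labels)
  if (is.null(bounds)) {
    stop_dot("no bounds supplied or attached", class = "dot_normalization_error")
  }
  rng <- bounds["max", ] - bounds["min", ]
  out <- sweep(sweep(labels, 2, rng, "*"), 2, bounds["min", ], "+")
  colnames(out) <- colnames(bounds)
  attr(out, "bounds") <- NULL
  out
}

#' Log-transform detector readings into regression features
#'
#' @param m a `measurement_set` (or a positive numeric matrix of readings).
#' @return matrix of natural-log readings.
#' @export
log_features <- function(m) {
  readings <- if (inherits(m, "measurement_set")) m$readings else rbind(m)
  if (any(readings <= 0) || any(!is.finite(readings))) {
    stop_dot("all readings must be positive and finite before log transform",
             class = "dot_domain_error")
  }
  log(readings)
}

#' Generate a labeled CW-DOT training corpus
#'
#' Draws `n_samples` seeded tumors in the phantom, simulates the transmission
#' measurement for each, adds multiplicative Gaussian noise, and stores the
#' natural-log readings as features together with the raw 5-column label
#' matrix `(x, y, z, mu_a, radius)`. Samples whose forward simulation fails
#' are resampled (up to `max_retries` each) and counted in the
#' `n_rejected` field.
#'
#' @param phantom a `slab_phantom`.
#' @param layout an `sd_layout`.
#' @param n_samples number of samples (the reference study condition
#'   is 5000; the desk-scale default pipeline uses 1000).
#' @param noise_level fractional noise (default 0.02).
#' @param seed master seed; every per-sample draw is derived from it.
#' @param contrast_range tumor contrast multiplier range.
#' @param n_nodes Born quadrature nodes per sample.
#' @param max_retries resampling attempts per slot before failing.
#' @return an object of class `labeled_dataset` with fields `features`
#'   (`n x n_channels`), `labels` (`n x 5`, physical units), `bounds`,
#'   `split` (NULL until [split_dataset()]), `seed`, `noise_level`,
#'   `n_rejected`.
#' @export
generate_dataset <- function(phantom, layout, n_samples, noise_level = 0.02,
                             seed = 1L, contrast_range = c(2, 4),
                             n_nodes = 500L, max_retries = 20L) {
  stopifnot(inherits(phantom, "slab_phantom"), inherits(layout, "sd_layout"))
  if (n_samples < 1) {
    stop_dot("n_samples must be >= 1", class = "dot_generation_error")
  }
  cache <- forward_cache(phantom, layout)
  n_channels <- nrow(cache$src) * nrow(cache$det)
  sample_seeds <- derive_seeds(seed, n_samples)
  features <- matrix(NA_real_, n_samples, n_channels)
  labels <- matrix(NA_real_, n_samples, 5,
                   dimnames = list(NULL, label_names))
  n_rejected <- 0L
  for (i in seq_len(n_samples)) {
    s <- sample_seeds[i]
    done <- FALSE
    for (try in 0:max_retries) {
      s_try <- (s + try * 7919L) %% .Machine$integer.max
      ok <- tryCatch({
        tumor <- sample_tumor(phantom, seed = s_try,
                              contrast_range = contrast_range)
        ms <- simulate_measurement(phantom, tumor, layout, n_nodes = n_nodes,
                                   seed = s_try, cache = cache)
        ms <- add_noise(ms, level = noise_level, seed = s_try)
        features[i, ] <- log_features(ms)
        labels[i, ] <- c(tumor$center_x, tumor$center_y, tumor$center_z,
                         tumor$mu_a_tumor, tumor$radius)
        TRUE
      }, dotinverse_error = function(e) FALSE)
      if (ok) { done <- TRUE; break }
      n_rejected <- n_rejected + 1L
    }
    if (!done) {
      stop_dot("sample %d failed after %d retries", i, max_retries,
               class = "dot_generation_error")
    }
  }
  structure(
    list(features = features, labels = labels,
         bounds = label_bounds(phantom, contrast_range = contrast_range),
         split = NULL, seed = as.integer(seed), noise_level = noise_level,
         n_rejected = n_rejected),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d channels, noise %.1f%%, %s\n",
              nrow(x$features), ncol(x$features), 100 * x$noise_level,
              if (is.null(x$split)) "unsplit" else "split"))
  invisible(x)
}

#' Partition a dataset between the boosting and GP stages
#'
#' A seeded random partition assigns `xgb_fraction` of the samples to the
#' gradient-boosting stage and the remainder to the GP stage; within each
#' stage, `train_fraction` are training samples and the rest test. With the
#' reference fractions (0.5 and 0.6) and n = 1000 this yields
#' 300/200/300/200 samples tagged `xgb-train`, `xgb-test`, `gp-train`,
#' `gp-test`.
#'
#' @param d a `labeled_dataset`.
#' @param xgb_fraction fraction of all samples given to the boosting stage.
#' @param train_fraction training fraction within each stage.
#' @param seed RNG seed for the permutation.
#' @return the dataset with a `split` character vector filled in.
#' @export
split_dataset <- function(d, xgb_fraction = 0.5, train_fraction = 0.6,
                          seed = 1L) {
  stopifnot(inherits(d, "labeled_dataset"))
  if (xgb_fraction <= 0 || xgb_fraction >= 1 ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop_dot("fractions must lie in (0, 1)", class = "dot_split_error")
  }
  n <- nrow(d$features)
  n_xgb <- round(n * xgb_fraction)
  n_gp <- n - n_xgb
  n_xgb_tr <- round(n_xgb * train_fraction)
  n_gp_tr <- round(n_gp * train_fraction)
  if (min(n_xgb_tr, n_xgb - n_xgb_tr, n_gp_tr, n_gp - n_gp_tr) < 1) {
    stop_dot("too few samples to populate all four splits",
             class = "dot_split_error")
  }
  perm <- with_seed(seed, sample.int(n))
  tags <- character(n)
  tags[perm[seq_len(n_xgb_tr)]] <- "xgb-train"
  tags[perm[n_xgb_tr + seq_len(n_xgb - n_xgb_tr)]] <- "xgb-test"
  tags[perm[n_xgb + seq_len(n_gp_tr)]] <- "gp-train"
  tags[perm[n_xgb + n_gp_tr + seq_len(n_gp - n_gp_tr)]] <- "gp-test"
  d$split <- tags
  d
}

#' Write a labeled dataset to a directory
#'
#' Persists features, labels and split tags as CSV plus a JSON metadata file
#' (seed, noise level, bounds, rejection count), giving a lossless,
#' text-format round trip with [read_dataset()].
#'
#' @param d a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # %.17g round-trips IEEE doubles exactly
  write_matrix_csv(d$features, file.path(dir, "features.csv"))
  write_matrix_csv(d$labels, file.path(dir, "labels.csv"))
  if (!is.null(d$split)) {
    writeLines(d$split, file.path(dir, "split.txt"))
  }
  meta <- list(seed = d$seed, noise_level = d$noise_level,
               n_rejected = d$n_rejected,
               bounds = list(min = unname(d$bounds["min", ]),
                             max = unname(d$bounds["max", ]),
                             labels = colnames(d$bounds)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `labeled_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  features <- as.matrix(utils::read.csv(file.path(dir, "features.csv")))
  dimnames(features) <- NULL
  labels <- as.matrix(utils::read.csv(file.path(dir, "labels.csv")))
  bounds <- rbind(min = meta$bounds$min, max = meta$bounds$max)
  colnames(bounds) <- meta$bounds$labels
  split <- NULL
  sp <- file.path(dir, "split.txt")
  if (file.exists(sp)) split <- readLines(sp)
  structure(
    list(features = features, labels = labels, bounds = bounds,
         split = split, seed = as.integer(meta$seed),
         noise_level = meta$noise_level,
         n_rejected = as.integer(meta$n_rejected)),
    class = "labeled_dataset"
  )
}
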