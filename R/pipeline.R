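#' Default pipeline configuration
#'
#' Two presets: `"desk"` (n = 1000 samples, GP population 500, 30
#' generations, 3 runs, 3 pipeline seeds) sized for interactive use and the
#' package's own evaluation, and `"paper"` (n = 5000, GP population 10,000,
#' 100 generations, 30 runs) matching the reference study budget, which
#' requires hours of CPU.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param seed base seed; the per-run pipeline seeds are `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return a nested configuration list of class `run_config`.
#' @export
default_config <- function(scale = c("desk", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  seed <- as.integer(seed)
  structure(list(
    scale = scale,
    phantom = list(size_x = 220.8, size_y = 102.9, size_z = 23.7,
                   mu_a = 0.005, mu_s_prime = 1.0, refractive_index = 1.4,
                   heterogeneity_amplitude = 0.1, seed = 1L),
    layout = list(n_sources = 48L, n_detectors = 54L, margin = 10),
    dataset = list(n_samples = if (desk) 1000L else 5000L,
                   noise_level = 0.02, contrast_range = c(2, 4),
                   n_nodes = 500L, xgb_fraction = 0.5, train_fraction = 0.6),
    gbm = list(nrounds = 500L, max_depth = 6L, learning_rate = 0.05,
               subsample = 0.8, max_bin = 32L),
    gp = list(population_size = if (desk) 500L else 10000L,
              generations = if (desk) 30L else 100L,
              n_runs = if (desk) 3L else 30L,
              p_reproduction = 0.35, p_crossover = 0.5, p_mutation = 0.15,
              tournament_size = 4L, fitness_subsample_fraction = 0.1),
    eval = list(seeds = seed + 0:2)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file are filled from [default_config()] for the
#' file's `scale` (default desk).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_dot("config file '%s' not found", path, class = "dot_config_error")
  }
  user <- yaml::read_yaml(path)
  base <- default_config(scale = user$scale %||% "desk")
  cfg <- utils::modifyList(unclass(base), user)
  class(cfg) <- "run_config"
  cfg
}

config_phantom <- function(config) {
  p <- config$phantom
  make_slab_phantom(p$size_x, p$size_y, p$size_z,
                    background = optical_properties(p$mu_a, p$mu_s_prime,
                                                    p$refractive_index),
                    heterogeneity_amplitude = p$heterogeneity_amplitude,
                    seed = p$seed)
}

# one seeded pass: simulate -> split -> boost -> evolve -> correct
run_pipeline_once <- function(config, phantom, layout, seed) {
  ds <- derive_seeds(seed, 4L)
  dcfg <- config$dataset
  d <- generate_dataset(phantom, layout, n_samples = dcfg$n_samples,
                        noise_level = dcfg$noise_level, seed = ds[1],
                        contrast_range = dcfg$contrast_range,
                        n_nodes = dcfg$n_nodes)
  d <- split_dataset(d, xgb_fraction = dcfg$xgb_fraction,
                     train_fraction = dcfg$train_fraction, seed = ds[2])
  model <- train_inverse_model(d, params = config$gbm, seed = ds[3])
  labels_norm <- normalize_labels(d$labels, d$bounds)
  sel <- function(tag) d$split == tag
  pred_xgb_test <- predict(model, d$features[sel("xgb-test"), , drop = FALSE])
  pred_gp_train <- predict(model, d$features[sel("gp-train"), , drop = FALSE])
  pred_gp_test <- predict(model, d$features[sel("gp-test"), , drop = FALSE])
  gcfg <- config$gp
  gp_cfg <- gp_config(population_size = gcfg$population_size,
                      generations = gcfg$generations,
                      p_reproduction = gcfg$p_reproduction,
                      p_crossover = gcfg$p_crossover,
                      p_mutation = gcfg$p_mutation,
                      tournament_size = gcfg$tournament_size,
                      fitness_subsample_fraction =
                        gcfg$fitness_subsample_fraction,
                      n_runs = gcfg$n_runs, seed = ds[4])
  corrections <- evolve_corrections(pred_gp_train,
                                    labels_norm[sel("gp-train"), , drop = FALSE],
                                    gp_cfg)
  list(
    seed = seed,
    bounds = d$bounds,
    n_rejected = d$n_rejected,
    truth_xgb_test = labels_norm[sel("xgb-test"), , drop = FALSE],
    truth_gp_test = labels_norm[sel("gp-test"), , drop = FALSE],
    pred_xgb_test = pred_xgb_test,
    pred_gp_test_raw = pred_gp_test,
    pred_gp_test_refined = refine_predictions(corrections, pred_gp_test),
    corrections = corrections
  )
}

#' Run the full simulate-train-refine-evaluate pipeline
#'
#' Executes, for every seed in `config$eval$seeds`: dataset simulation,
#' stage splitting, per-label boosted-tree training, per-label GP correction
#' evolution, and evaluation. Returns three reports aggregated across seeds:
#' `after_xgb` (stage-one predictions on the `xgb-test` split),
#' `after_xgb_on_gp_test` (uncorrected stage-one predictions on the
#' `gp-test` split, the baseline the GP must not worsen) and `after_gp`
#' (GP-corrected predictions on the `gp-test` split).
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir optional directory; when given, the reports, the evolved
#'   correction programs (prefix s-expressions) and the GP fitness histories
#'   are written there as JSON/CSV.
#' @return an object of class `pipeline_result` with the three
#'   `evaluation_report`s, the per-seed raw results, the config and its hash.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  phantom <- config_phantom(config)
  layout <- make_layout(phantom, config$layout$n_sources,
                        config$layout$n_detectors, config$layout$margin)
  seeds <- config$eval$seeds
  runs <- lapply(seeds, function(s) run_pipeline_once(config, phantom,
                                                      layout, s))
  bounds <- runs[[1]]$bounds
  after_xgb <- evaluate_stage(lapply(runs, `[[`, "pred_xgb_test"),
                              lapply(runs, `[[`, "truth_xgb_test"),
                              stage = "after-xgb", bounds = bounds,
                              seeds = seeds)
  baseline <- evaluate_stage(lapply(runs, `[[`, "pred_gp_test_raw"),
                             lapply(runs, `[[`, "truth_gp_test"),
                             stage = "after-xgb-on-gp-test", bounds = bounds,
                             seeds = seeds)
  after_gp <- evaluate_stage(lapply(runs, `[[`, "pred_gp_test_refined"),
                             lapply(runs, `[[`, "truth_gp_test"),
                             stage = "after-gp", bounds = bounds,
                             seeds = seeds)
  result <- structure(
    list(after_xgb = after_xgb, after_xgb_on_gp_test = baseline,
         after_gp = after_gp, runs = runs, config = config,
         config_hash = config_hash(config),
         n_rejected = sum(vapply(runs, `[[`, integer(1), "n_rejected"))),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s scale, seeds %s, config %s\n",
              x$config$scale, paste(x$config$eval$seeds, collapse = "/"),
              substr(x$config_hash, 1, 8)))
  print(x$after_xgb)
  print(x$after_gp)
  invisible(x)
}

#' Write pipeline reports and artifacts to a directory
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package_version = as.character(utils::packageVersion("dotinverse")),
               config_hash = result$config_hash,
               seeds = result$config$eval$seeds,
               n_rejected = result$n_rejected)
  report <- list(meta = meta,
                 after_xgb = report_to_list(result$after_xgb),
                 after_xgb_on_gp_test = report_to_list(result$after_xgb_on_gp_test),
                 after_gp = report_to_list(result$after_gp))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  trees <- lapply(result$runs, function(r) {
    lapply(r$corrections, function(g) tree_to_sexp(g$best_tree))
  })
  names(trees) <- paste0("seed_", vapply(result$runs, `[[`, numeric(1), "seed"))
  jsonlite::write_json(list(meta = meta, corrections = trees),
                       file.path(out_dir, "corrections.json"),
                       auto_unbox = TRUE, digits = NA)
  hist_rows <- do.call(rbind, lapply(result$runs, function(r) {
    do.call(rbind, lapply(seq_along(r$corrections), function(k) {
      h <- r$corrections[[k]]$fitness_history
      data.frame(seed = r$seed, label = label_names[k],
                 run = rep(seq_len(ncol(h)), each = nrow(h)),
                 generation = rep(seq_len(nrow(h)), ncol(h)),
                 best_rmse = as.numeric(h))
    }))
  }))
  utils::write.csv(hist_rows, file.path(out_dir, "fitness_history.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Markdown summary table of the two stages
#'
#' @param result a `pipeline_result`.
#' @return character vector of Markdown lines (also printed invisibly).
#' @export
summary_table <- function(result) {
  a <- result$after_xgb$per_label_rmse
  g <- result$after_gp$per_label_rmse
  lines <- c(
    "| Label | RMSE (after XGBoost) | RMSE (after GP) |",
    "|-------|----------------------|-----------------|",
    vapply(seq_along(label_names), function(k) {
      sprintf("| %s | %.4f ± %.4f | %.4f ± %.4f |",
              label_names[k], a$mean[k], a$sd[k], g$mean[k], g$sd[k])
    }, character(1))
  )
  lines
}
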