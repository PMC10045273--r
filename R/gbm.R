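#' Fit the stage-one boosted-tree inverse model
#'
#' Trains one gradient-boosted regression-tree ensemble (squared-error
#' objective) per tumor label — x, y, z, absorption coefficient, radius —
#' mapping the log-readings of the `xgb-train` split to the min-max
#' normalized label. Five independent scalar regressors are used because the
#' label components live on very different physical scales and the reference
#' protocol regresses each one separately.
#'
#' @param d a split `labeled_dataset` (see [split_dataset()]).
#' @param params list of hyperparameters: `nrounds`, `max_depth`,
#'   `learning_rate`, `subsample` (defaults 500, 6, 0.05, 0.8) and the
#'   histogram resolution `max_bin` (default 32; the log-fluence features
#'   are smooth, so coarse bins lose nothing while training much faster).
#' @param seed seed forwarded to the booster for subsampling.
#' @return an object of class `trained_inverse_model`: five fitted boosters
#'   (in label order x, y, z, mu_a, radius), the hyperparameters, the label
#'   bounds and the training-feature width.
#' @export
train_inverse_model <- function(d, params = list(), seed = 1L) {
  stopifnot(inherits(d, "labeled_dataset"))
  if (is.null(d$split) || !any(d$split == "xgb-train")) {
    stop_dot("dataset has no xgb-train split", class = "dot_training_error")
  }
  hp <- utils::modifyList(
    list(nrounds = 500L, max_depth = 6L, learning_rate = 0.05,
         subsample = 0.8, max_bin = 32L),
    params
  )
  idx <- which(d$split == "xgb-train")
  x <- d$features[idx, , drop = FALSE]
  y <- normalize_labels(d$labels[idx, , drop = FALSE], d$bounds)
  models <- vector("list", 5L)
  names(models) <- label_names
  for (k in seq_len(5L)) {
    dm <- xgboost::xgb.DMatrix(x, label = y[, k], nthread = 1)
    models[[k]] <- xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "reg:squarederror",
        max_depth = hp$max_depth,
        learning_rate = hp$learning_rate,
        subsample = hp$subsample,
        max_bin = hp$max_bin,
        nthread = 1,
        seed = as.integer(seed)
      ),
      data = dm,
      nrounds = hp$nrounds,
      verbose = 0
    )
  }
  structure(
    list(per_label_models = models, hyperparameters = hp,
         bounds = d$bounds, n_features = ncol(x), seed = as.integer(seed)),
    class = "trained_inverse_model"
  )
}

#' @export
print.trained_inverse_model <- function(x, ...) {
  cat(sprintf(
    "<trained_inverse_model> 5 boosted-tree regressors (%d rounds, depth %d) on %d features\n",
    x$hyperparameters$nrounds, x$hyperparameters$max_depth, x$n_features))
  invisible(x)
}

#' Predict normalized tumor labels from log-readings
#'
#' @param object a `trained_inverse_model`.
#' @param features numeric matrix `n x n_features` of log-readings.
#' @param physical if `TRUE`, return labels denormalized to physical units
#'   instead of the normalized `[0, 1]` scale.
#' @param ... unused.
#' @return `n x 5` matrix of predictions (clipped to `[0, 1]` on the
#'   normalized scale).
#' @export
predict.trained_inverse_model <- function(object, features,
                                          physical = FALSE, ...) {
  features <- rbind(features)
  if (ncol(features) != object$n_features) {
    stop_dot("feature width %d does not match training width %d",
             ncol(features), object$n_features, class = "dot_shape_error")
  }
  out <- vapply(
    object$per_label_models,
    function(m) stats::predict(m, features),
    numeric(nrow(features))
  )
  out <- matrix(out, nrow = nrow(features),
                dimnames = list(NULL, label_names))
  out <- pmin(pmax(out, 0), 1)
  if (physical) denormalize_labels(out, object$bounds) else out
}
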