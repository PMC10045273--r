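#' Root mean square error
#'
#' `sqrt(mean((y - x)^2))`; symmetric in its arguments.
#'
#' @param predictions,truths aligned numeric vectors (or matrices, flattened).
#' @return scalar RMSE.
#' @examples
#' rmse(c(2, 4, 6), c(1, 2, 3))  # sqrt(14/3)
#' @export
rmse <- function(predictions, truths) {
  if (length(predictions) == 0L || length(predictions) != length(truths)) {
    stop_dot("rmse needs non-empty aligned inputs",
             class = "dot_evaluation_error")
  }
  sqrt(mean((as.numeric(predictions) - as.numeric(truths))^2))
}

#' Cosine similarity of two vectors
#'
#' `dot(x, y) / (|x| |y|)`, in `[-1, 1]`.
#'
#' @param x_vec,y_vec aligned non-zero numeric vectors.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(x_vec, y_vec) {
  stopifnot(length(x_vec) == length(y_vec))
  nx <- sqrt(sum(x_vec^2))
  ny <- sqrt(sum(y_vec^2))
  if (nx == 0 || ny == 0) {
    stop_dot("cosine similarity undefined for a zero vector",
             class = "dot_evaluation_error")
  }
  sum(x_vec * y_vec) / (nx * ny)
}

per_label_rmse <- function(pred, truth) {
  vapply(seq_len(ncol(pred)), function(k) rmse(pred[, k], truth[, k]),
         numeric(1))
}

mean_sample_cs <- function(pred, truth) {
  mean(vapply(seq_len(nrow(pred)),
              function(i) cosine_similarity(pred[i, ], truth[i, ]),
              numeric(1)))
}

#' Evaluate a pipeline stage
#'
#' Computes the five per-label RMSEs (normalized scale and, if `bounds` is
#' given, physical units) and the mean per-sample cosine similarity between
#' predicted and true normalized label 5-vectors. When `predictions` /
#' `truths` are lists (one matrix per repeated seeded run), each quantity is
#' reported as mean and standard deviation across runs.
#'
#' @param predictions `n x 5` normalized prediction matrix or list of such
#'   matrices (one per run).
#' @param truths matching truth matrix or list.
#' @param stage tag, e.g. `"after-xgb"` or `"after-gp"`.
#' @param bounds optional `2 x 5` label bounds for physical-unit RMSE.
#' @param seeds optional seeds the runs used (recorded in the report).
#' @return an object of class `evaluation_report` with fields
#'   `per_label_rmse` (`mean`, `sd`, 5 each, label order x, y, z, mu_a,
#'   radius), `per_label_rmse_physical`, `mean_cosine_similarity`
#'   (`mean`, `sd`), `stage`, `n_test`, `n_runs`, `seeds`.
#' @export
evaluate_stage <- function(predictions, truths, stage = "after-xgb",
                           bounds = NULL, seeds = NULL) {
  preds <- if (is.list(predictions)) predictions else list(predictions)
  trs <- if (is.list(truths)) truths else list(truths)
  if (length(preds) != length(trs) || length(preds) == 0L) {
    stop_dot("predictions and truths must be aligned non-empty",
             class = "dot_shape_error")
  }
  rm_runs <- matrix(NA_real_, length(preds), 5L,
                    dimnames = list(NULL, label_names))
  cs_runs <- numeric(length(preds))
  for (r in seq_along(preds)) {
    p <- rbind(preds[[r]])
    t <- rbind(trs[[r]])
    if (!all(dim(p) == dim(t)) || ncol(p) != 5L) {
      stop_dot("each run needs matching n x 5 matrices",
               class = "dot_shape_error")
    }
    rm_runs[r, ] <- per_label_rmse(p, t)
    cs_runs[r] <- mean_sample_cs(p, t)
  }
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  rng <- if (!is.null(bounds)) bounds["max", ] - bounds["min", ] else NULL
  structure(
    list(
      per_label_rmse = list(mean = colMeans(rm_runs),
                            sd = apply(rm_runs, 2, sd0)),
      per_label_rmse_physical = if (is.null(rng)) NULL else {
        list(mean = colMeans(rm_runs) * rng,
             sd = apply(rm_runs, 2, sd0) * rng)
      },
      mean_cosine_similarity = list(mean = mean(cs_runs), sd = sd0(cs_runs)),
      stage = stage,
      n_test = nrow(rbind(preds[[1]])),
      n_runs = length(preds),
      seeds = seeds
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> stage %s, n_test = %d, runs = %d\n",
              x$stage, x$n_test, x$n_runs))
  for (k in seq_along(label_names)) {
    cat(sprintf("  RMSE %-7s %.4f +/- %.4f (normalized)\n", label_names[k],
                x$per_label_rmse$mean[k], x$per_label_rmse$sd[k]))
  }
  cat(sprintf("  mean cosine similarity %.4f +/- %.4f\n",
              x$mean_cosine_similarity$mean, x$mean_cosine_similarity$sd))
  invisible(x)
}

#' Convert an evaluation report to a plain list (for JSON)
#' @param report an `evaluation_report`.
#' @return a list mirroring the report fields.
#' @export
report_to_list <- function(report) {
  unclass(report)
}

#' Render a reconstruction slice
#'
#' Rasterizes the absorption map of a predicted (or true) tumor on the plane
#' `z = z_slice`: the background absorption everywhere, the tumor absorption
#' inside the circle where the sphere intersects the slice (radius
#' `sqrt(r^2 - d^2)` at distance `d < r` from the center plane).
#'
#' @param labels_row length-5 numeric vector `(x, y, z, mu_a, radius)` in
#'   physical units.
#' @param phantom a `slab_phantom`.
#' @param z_slice slice height, mm, in `[0, size_z]`.
#' @param grid_resolution raster pixel size, mm.
#' @return numeric matrix (x along rows, y along columns) of absorption
#'   values with attributes `x` and `y` giving the pixel-center coordinates.
#' @export
render_reconstruction <- function(labels_row, phantom, z_slice,
                                  grid_resolution = 1) {
  stopifnot(inherits(phantom, "slab_phantom"), length(labels_row) == 5L)
  if (z_slice < 0 || z_slice > phantom$size_z) {
    stop_dot("z_slice must lie within [0, %g]", phantom$size_z,
             class = "dot_range_error")
  }
  xs <- seq(grid_resolution / 2, phantom$size_x, by = grid_resolution)
  ys <- seq(grid_resolution / 2, phantom$size_y, by = grid_resolution)
  img <- matrix(phantom$background$mu_a, length(xs), length(ys))
  d <- abs(z_slice - labels_row[3])
  r <- labels_row[5]
  if (d < r) {
    disk_r <- sqrt(r^2 - d^2)
    dist2 <- outer((xs - labels_row[1])^2, (ys - labels_row[2])^2, "+")
    img[dist2 <= disk_r^2] <- labels_row[4]
  }
  attr(img, "x") <- xs
  attr(img, "y") <- ys
  img
}
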