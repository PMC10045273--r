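#' Diffusion parameters derived from optical properties
#'
#' Computes the diffusion coefficient `D = 1/(3 (mu_a + mu_s'))`, the
#' effective attenuation `mu_eff = sqrt(mu_a / D)` and the extrapolated
#' boundary distance `z_b = 2 A D`, where `A` accounts for internal
#' reflection at the tissue-air interface via the Groenhuis polynomial
#' approximation of the effective reflection coefficient.
#'
#' @param optics an `optical_properties` object.
#' @return an object of class `diffusion_params` with fields `D` (mm),
#'   `mu_eff` (mm^-1), `z_b` (mm) and `A`.
#' @export
diffusion_params <- function(optics) {
  stopifnot(inherits(optics, "optical_properties"))
  D <- 1 / (3 * (optics$mu_a + optics$mu_s_prime))
  mu_eff <- sqrt(optics$mu_a / D)
  n <- optics$refractive_index
  r_d <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + r_d) / (1 - r_d)
  structure(list(D = D, mu_eff = mu_eff, z_b = 2 * A * D, A = A),
            class = "diffusion_params")
}

#' CW fluence of a point source in an infinite diffusive medium
#'
#' The closed form `exp(-mu_eff r) / (4 pi D r)`.
#'
#' @param optics `optical_properties`.
#' @param r source-field distance(s), mm (> 0).
#' @return fluence per unit source power, mm^-2 (vectorized over `r`).
#' @examples
#' infinite_medium_fluence(optical_properties(0.01, 1.0), 10)
#' @export
infinite_medium_fluence <- function(optics, r) {
  dp <- diffusion_params(optics)
  if (any(r <= 0)) {
    stop_dot("source-field distance must be > 0", class = "dot_singularity_error")
  }
  exp(-dp$mu_eff * r) / (4 * pi * dp$D * r)
}

# image-source Green's function between interior points of a slab,
# vectorized over rows of `field_points`; `dp` precomputed for speed.
# The m and -m image contributions are paired before accumulation: swapping
# the two endpoints maps the positive-image term at m onto the one at -m
# (and leaves each negative-image term unchanged), so with this pairing the
# truncated series is bit-identical under the swap — reciprocity is exact,
# not just approximate.
slab_green <- function(dp, slab_thickness, source_point, field_points,
                       n_pairs = 7L, check_convergence = FALSE) {
  fp <- rbind(field_points)
  rho2 <- (fp[, 1] - source_point[1])^2 + (fp[, 2] - source_point[2])^2
  zs <- source_point[3]
  z <- fp[, 3]
  Lz <- slab_thickness + 2 * dp$z_b
  scale <- 4 * pi * dp$D
  term_plus <- function(m) {
    r <- sqrt(rho2 + (z - zs - 2 * m * Lz)^2)
    exp(-dp$mu_eff * r) / (scale * r)
  }
  term_minus <- function(m) {
    r <- sqrt(rho2 + (z + zs + 2 * dp$z_b - 2 * m * Lz)^2)
    exp(-dp$mu_eff * r) / (scale * r)
  }
  plus_sum <- term_plus(0L)
  minus_sum <- term_minus(0L)
  last <- 0
  for (m in seq_len(n_pairs)) {
    dplus <- term_plus(m) + term_plus(-m)
    dminus <- term_minus(m) + term_minus(-m)
    plus_sum <- plus_sum + dplus
    minus_sum <- minus_sum + dminus
    if (m == n_pairs) last <- dplus - dminus
  }
  total <- plus_sum - minus_sum
  if (check_convergence &&
      any(abs(last) > 1e-9 * pmax(abs(total), .Machine$double.xmin))) {
    warning("image-source series may not have converged; increase n_pairs")
  }
  total
}

#' CW fluence between two points in a diffusive slab
#'
#' Image-source solution of the diffusion equation for an infinite slab with
#' extrapolated (zero-fluence) boundaries at `z = -z_b` and
#' `z = thickness + z_b`. The mirror series is truncated at `n_pairs` image
#' pairs on each side; the truncation is symmetric, so the truncated Green's
#' function is exactly reciprocal in its two arguments.
#'
#' @param optics `optical_properties`.
#' @param slab_thickness slab thickness, mm.
#' @param source_point,field_point numeric length-3 positions, mm
#'   (`field_point` may be an `n x 3` matrix).
#' @param n_pairs number of image pairs kept on each side of the slab.
#' @param check_convergence if `TRUE`, warn when the outermost image pair
#'   still contributes more than 1e-9 of the running sum.
#' @return fluence, mm^-2 (vector of `nrow(field_point)` values).
#' @export
slab_fluence <- function(optics, slab_thickness, source_point, field_point,
                         n_pairs = 7L, check_convergence = FALSE) {
  dp <- diffusion_params(optics)
  slab_green(dp, slab_thickness, source_point, field_point,
             n_pairs = n_pairs, check_convergence = check_convergence)
}

# seeded uniform quadrature nodes inside a sphere (n x 3 matrix)
sphere_nodes <- function(tumor, n_nodes, seed) {
  with_seed(seed, {
    u <- stats::runif(n_nodes)
    r <- tumor$radius * u^(1 / 3)
    ct <- stats::runif(n_nodes, -1, 1)
    st <- sqrt(1 - ct^2)
    ang <- stats::runif(n_nodes, 0, 2 * pi)
    cbind(tumor$center_x + r * st * cos(ang),
          tumor$center_y + r * st * sin(ang),
          tumor$center_z + r * ct)
  })
}

# shared core: fractional first-order (Born) perturbation for all
# source x detector pairs; sources/detectors are n x 3 matrices of the
# *effective* (already depth-shifted) source positions
born_matrix <- function(dp, tumor, source_points, detector_points,
                        slab_thickness, nodes, g_background = NULL) {
  delta_mu <- tumor$mu_a_tumor_delta
  ns <- nrow(source_points)
  nd <- nrow(detector_points)
  nq <- nrow(nodes)
  gs <- matrix(0, ns, nq)
  for (i in seq_len(ns)) {
    gs[i, ] <- slab_green(dp, slab_thickness, source_points[i, ], nodes)
  }
  gd <- matrix(0, nd, nq)
  for (j in seq_len(nd)) {
    gd[j, ] <- slab_green(dp, slab_thickness, detector_points[j, ], nodes)
  }
  if (is.null(g_background)) {
    g_background <- matrix(0, ns, nd)
    for (i in seq_len(ns)) {
      g_background[i, ] <- slab_green(dp, slab_thickness, source_points[i, ],
                                      detector_points)
    }
  }
  vol <- 4 / 3 * pi * tumor$radius^3
  w <- vol / nq
  -(delta_mu * w / dp$D) * (gs %*% t(gd)) / g_background
}

#' First-order Born perturbation of a single transmission channel
#'
#' Fractional change in the detected CW intensity caused by a spherical
#' absorber, to first order in the absorption contrast:
#' `-(1/D) * integral over the sphere of dmu_a G(s->r') G(r'->d) dV / G(s->d)`.
#' The volume integral uses seeded uniform Monte Carlo nodes inside the
#' sphere. The result is `<= 0` whenever the tumor absorbs more than the
#' background (an absorber can only remove light).
#'
#' @param optics background `optical_properties`.
#' @param tumor a `tumor_spec`.
#' @param source_point,detector_point length-3 positions, mm.
#' @param slab_thickness slab thickness, mm.
#' @param n_nodes quadrature nodes inside the sphere (default 500).
#' @param seed seed for the node placement.
#' @return scalar fractional intensity change (dimensionless).
#' @export
born_perturbation <- function(optics, tumor, source_point, detector_point,
                              slab_thickness, n_nodes = 500L, seed = 1L) {
  stopifnot(inherits(tumor, "tumor_spec"))
  if (tumor$center_z < tumor$radius ||
      tumor$center_z > slab_thickness - tumor$radius) {
    stop_dot("tumor sphere overlaps a slab face", class = "dot_geometry_error")
  }
  dp <- diffusion_params(optics)
  tum <- tumor
  tum$mu_a_tumor_delta <- tumor$mu_a_tumor - optics$mu_a
  nodes <- sphere_nodes(tumor, n_nodes, seed)
  as.numeric(born_matrix(dp, tum, rbind(source_point), rbind(detector_point),
                         slab_thickness, nodes))
}

# Precompute everything about a phantom + layout that does not depend on the
# tumor: effective source points (one transport mean free path inside the
# slab), the background channel Green's functions, and the per-channel
# heterogeneity attenuation factors along the source-detector chord.
forward_cache <- function(phantom, layout, n_pairs = 7L) {
  optics <- phantom$background
  dp <- diffusion_params(optics)
  src <- layout$source_positions
  src[, 3] <- src[, 3] + 1 / optics$mu_s_prime
  det <- layout$detector_positions
  ns <- nrow(src)
  nd <- nrow(det)
  g_bg <- matrix(0, ns, nd)
  for (i in seq_len(ns)) {
    g_bg[i, ] <- slab_green(dp, phantom$size_z, src[i, ], det,
                            n_pairs = n_pairs)
  }
  het <- matrix(1, ns, nd)
  if (phantom$heterogeneity_amplitude > 0) {
    tq <- seq(0, 1, length.out = 21L)
    for (i in seq_len(ns)) {
      for (j in seq_len(nd)) {
        chord <- outer(tq, det[j, ] - src[i, ]) +
          matrix(src[i, ], length(tq), 3, byrow = TRUE)
        h_mean <- mean(heterogeneity_field(phantom, chord))
        mu_a_loc <- optics$mu_a * h_mean
        mu_eff_loc <- sqrt(mu_a_loc / dp$D)
        len <- sqrt(sum((det[j, ] - src[i, ])^2))
        het[i, j] <- exp(-(mu_eff_loc - dp$mu_eff) * len)
      }
    }
  }
  channel_index <- expand.grid(source = seq_len(ns), detector = seq_len(nd))
  list(dp = dp, src = src, det = det, g_bg = g_bg, het = het,
       thickness = phantom$size_z, n_pairs = n_pairs,
       channel_index = channel_index)
}

#' Simulate a CW transmission measurement of a tumor-bearing slab
#'
#' For every source-detector channel the detected intensity is the background
#' slab fluence scaled by `exp(born)` — the first-order (Rytov-type)
#' exponential of the normalized Born integral, which agrees with
#' `1 + born` for small perturbations while remaining strictly positive for
#' strong absorbers — and by the heterogeneity attenuation along the chord.
#'
#' @param phantom a `slab_phantom`.
#' @param tumor a `tumor_spec` (or `NULL` for a tumor-free measurement).
#' @param layout an `sd_layout`.
#' @param n_nodes Born quadrature nodes (default 500).
#' @param seed seed for the quadrature node placement.
#' @param cache optional precomputed `forward_cache()`; pass one when
#'   simulating many tumors in the same geometry.
#' @return an object of class `measurement_set` with a `1 x n_channels`
#'   `readings` matrix, a `channel_index` data frame and `noise_level = 0`.
#' @export
simulate_measurement <- function(phantom, tumor, layout, n_nodes = 500L,
                                 seed = 1L, cache = NULL) {
  stopifnot(inherits(phantom, "slab_phantom"), inherits(layout, "sd_layout"))
  if (is.null(cache)) cache <- forward_cache(phantom, layout)
  readings <- cache$g_bg * cache$het
  if (!is.null(tumor)) {
    stopifnot(inherits(tumor, "tumor_spec"))
    tum <- tumor
    tum$mu_a_tumor_delta <- tumor$mu_a_tumor - phantom$background$mu_a
    nodes <- sphere_nodes(tumor, n_nodes, seed)
    pert <- born_matrix(cache$dp, tum, cache$src, cache$det, cache$thickness,
                        nodes, g_background = cache$g_bg)
    readings <- readings * exp(pert)
  }
  flat <- as.numeric(readings)  # column-major: source index varies fastest
  if (any(!is.finite(flat)) || any(flat <= 0)) {
    stop_dot("forward model produced non-positive or non-finite readings",
             class = "dot_forward_error")
  }
  structure(
    list(readings = matrix(flat, nrow = 1),
         channel_index = cache$channel_index,
         noise_level = 0),
    class = "measurement_set"
  )
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d sample(s) x %d channels, noise %.1f%%\n",
              nrow(x$readings), ncol(x$readings), 100 * x$noise_level))
  invisible(x)
}

#' Add multiplicative Gaussian measurement noise
#'
#' Every reading is multiplied by `1 + e`, `e ~ Normal(0, level)`, emulating
#' proportional detector error (the study condition is `level = 0.02`, i.e.
#' 2% Gaussian noise). Results are clipped to stay positive.
#'
#' @param m a `measurement_set`.
#' @param level fractional noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return a `measurement_set` with noisy readings and `noise_level = level`.
#' @export
add_noise <- function(m, level = 0.02, seed = 1L) {
  stopifnot(inherits(m, "measurement_set"))
  if (!is.numeric(level) || length(level) != 1L || level < 0) {
    stop_dot("noise level must be a single number >= 0",
             class = "dot_parameter_error")
  }
  if (level == 0) return(m)
  eps <- with_seed(seed, stats::rnorm(length(m$readings), 0, level))
  noisy <- m$readings * (1 + eps)
  m$readings <- pmax(noisy, m$readings * 1e-6)
  m$noise_level <- level
  m
}
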