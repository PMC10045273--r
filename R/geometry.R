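#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient and
#' refractive index of a homogeneous diffusive medium. The diffusion
#' approximation requires scattering to dominate absorption; a warning is
#' emitted when `mu_a / mu_s_prime > 0.1`.
#'
#' Defaults are typical of healthy breast tissue in the near-infrared window
#' around 800 nm: `mu_a = 0.005` mm^-1, `mu_s_prime = 1.0` mm^-1, `n = 1.4`.
#'
#' @param mu_a absorption coefficient, mm^-1 (> 0).
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0).
#' @param refractive_index refractive index (>= 1).
#' @return an object of class `optical_properties`.
#' @examples
#' optical_properties()
#' optical_properties(mu_a = 0.01, mu_s_prime = 1.2)
#' @export
optical_properties <- function(mu_a = 0.005, mu_s_prime = 1.0,
                               refractive_index = 1.4) {
  if (!is.numeric(mu_a) || length(mu_a) != 1L || mu_a <= 0) {
    stop_dot("mu_a must be a single positive number", class = "dot_optics_error")
  }
  if (!is.numeric(mu_s_prime) || length(mu_s_prime) != 1L || mu_s_prime <= 0) {
    stop_dot("mu_s_prime must be a single positive number",
             class = "dot_optics_error")
  }
  if (!is.numeric(refractive_index) || length(refractive_index) != 1L ||
      refractive_index < 1) {
    stop_dot("refractive_index must be >= 1", class = "dot_optics_error")
  }
  if (mu_a / mu_s_prime > 0.1) {
    warning("mu_a/mu_s_prime > 0.1: diffusion approximation is questionable")
  }
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime,
         refractive_index = refractive_index),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mu_a = %g mm^-1, mu_s' = %g mm^-1, n = %g\n",
    x$mu_a, x$mu_s_prime, x$refractive_index))
  invisible(x)
}

#' Compressed-breast slab phantom
#'
#' A rectangular slab with homogeneous background optics and, optionally, a
#' smooth seeded multiplicative heterogeneity field on the absorption
#' coefficient emulating the spatially varying glandularity of real breast
#' tissue. The field is a fixed sum of low-frequency cosine modes whose
#' combined modulation is bounded by `heterogeneity_amplitude`, so the local
#' absorption stays within `(1 +/- amplitude) * mu_a`.
#'
#' @param size_x,size_y,size_z slab extents in mm. Defaults are the
#'   compressed-breast dimensions 220.8 x 102.9 x 23.7 mm.
#' @param background `optical_properties` of the bulk tissue.
#' @param heterogeneity_amplitude fractional modulation of the background
#'   absorption, in `[0, 0.5)`. `0` gives a homogeneous slab.
#' @param seed seed for the heterogeneity field.
#' @return an object of class `slab_phantom`.
#' @examples
#' ph <- make_slab_phantom()
#' ph$size_x
#' @export
make_slab_phantom <- function(size_x = 220.8, size_y = 102.9, size_z = 23.7,
                              background = optical_properties(),
                              heterogeneity_amplitude = 0.1,
                              seed = 1L) {
  sizes <- c(size_x, size_y, size_z)
  if (!is.numeric(sizes) || length(sizes) != 3L || any(!is.finite(sizes)) ||
      any(sizes <= 0)) {
    stop_dot("slab extents must all be positive", class = "dot_dimension_error")
  }
  stopifnot(inherits(background, "optical_properties"))
  if (!is.numeric(heterogeneity_amplitude) || heterogeneity_amplitude < 0 ||
      heterogeneity_amplitude >= 0.5) {
    stop_dot("heterogeneity_amplitude must be in [0, 0.5)",
             class = "dot_dimension_error")
  }
  field <- NULL
  if (heterogeneity_amplitude > 0) {
    field <- with_seed(seed, {
      k <- 12L
      wavelength <- stats::runif(k, 20, 60)     # mm, glandularity-scale
      theta <- stats::runif(k, 0, 2 * pi)
      phi_dir <- acos(stats::runif(k, -1, 1))
      dirs <- cbind(sin(phi_dir) * cos(theta),
                    sin(phi_dir) * sin(theta),
                    cos(phi_dir))
      list(
        amps = stats::runif(k, 0.3, 1),
        kvec = dirs * (2 * pi / wavelength),
        phase = stats::runif(k, 0, 2 * pi)
      )
    })
  }
  structure(
    list(size_x = size_x, size_y = size_y, size_z = size_z,
         background = background,
         heterogeneity_amplitude = heterogeneity_amplitude,
         heterogeneity_seed = as.integer(seed),
         field = field),
    class = "slab_phantom"
  )
}

#' @export
print.slab_phantom <- function(x, ...) {
  cat(sprintf(
    "<slab_phantom> %.1f x %.1f x %.1f mm, bg mu_a = %g mm^-1, heterogeneity %.0f%%\n",
    x$size_x, x$size_y, x$size_z, x$background$mu_a,
    100 * x$heterogeneity_amplitude))
  invisible(x)
}

#' Evaluate the phantom heterogeneity field
#'
#' Returns the multiplicative absorption modulation `h(r)` at 3D points, with
#' `h = 1` everywhere for a homogeneous phantom and
#' `|h - 1| <= heterogeneity_amplitude` otherwise.
#'
#' @param phantom a `slab_phantom`.
#' @param points numeric matrix `n x 3` of positions in mm.
#' @return numeric vector of length `n`.
#' @export
heterogeneity_field <- function(phantom, points) {
  stopifnot(inherits(phantom, "slab_phantom"))
  points <- rbind(points)
  if (phantom$heterogeneity_amplitude == 0 || is.null(phantom$field)) {
    return(rep(1, nrow(points)))
  }
  f <- phantom$field
  raw <- cos(points %*% t(f$kvec) +
               matrix(f$phase, nrow(points), length(f$phase), byrow = TRUE))
  # normalized by the amplitude sum so the modulation bound is guaranteed
  1 + phantom$heterogeneity_amplitude * as.numeric(raw %*% f$amps) / sum(f$amps)
}

#' Spherical tumor specification
#'
#' @param center_x,center_y,center_z tumor center, mm.
#' @param radius tumor radius, mm (in `[2, 15]`).
#' @param mu_a_tumor tumor absorption coefficient, mm^-1.
#' @param phantom optional `slab_phantom` used to check containment.
#' @return an object of class `tumor_spec`.
#' @export
tumor_spec <- function(center_x, center_y, center_z, radius, mu_a_tumor,
                       phantom = NULL) {
  if (radius < 2 || radius > 15) {
    stop_dot("tumor radius must lie in [2, 15] mm", class = "dot_tumor_error")
  }
  if (!is.null(phantom)) {
    ok <- center_x >= radius && center_x <= phantom$size_x - radius &&
      center_y >= radius && center_y <= phantom$size_y - radius &&
      center_z >= radius && center_z <= phantom$size_z - radius
    if (!ok) {
      stop_dot("tumor sphere is not entirely inside the slab",
               class = "dot_tumor_error")
    }
    if (mu_a_tumor <= phantom$background$mu_a) {
      stop_dot("tumor mu_a must exceed the background mu_a",
               class = "dot_tumor_error")
    }
  }
  structure(
    list(center_x = center_x, center_y = center_y, center_z = center_z,
         radius = radius, mu_a_tumor = mu_a_tumor),
    class = "tumor_spec"
  )
}

#' @export
print.tumor_spec <- function(x, ...) {
  cat(sprintf(
    "<tumor_spec> center (%.1f, %.1f, %.1f) mm, r = %.2f mm, mu_a = %g mm^-1\n",
    x$center_x, x$center_y, x$center_z, x$radius, x$mu_a_tumor))
  invisible(x)
}

#' Draw a random tumor inside a slab phantom
#'
#' The radius is uniform on `[2, r_max]` mm where `r_max` is the largest
#' radius that can fit (at most 15 mm); the center is uniform over the
#' admissible interior (every face at distance >= radius); the tumor
#' absorption is uniform over `contrast_range * background mu_a`, reflecting
#' the elevated blood content of tumors.
#'
#' @param phantom a `slab_phantom`.
#' @param seed RNG seed.
#' @param contrast_range length-2 multiplier range on the background
#'   absorption for the tumor, default `c(2, 4)`.
#' @return a `tumor_spec`.
#' @export
sample_tumor <- function(phantom, seed = NULL, contrast_range = c(2, 4)) {
  stopifnot(inherits(phantom, "slab_phantom"))
  half_min <- min(phantom$size_x, phantom$size_y, phantom$size_z) / 2
  if (half_min < 2) {
    stop_dot("slab too thin to contain a radius-2 mm sphere",
             class = "dot_geometry_error")
  }
  draw <- function() {
    r_max <- min(15, half_min)
    r <- stats::runif(1, 2, r_max)
    cx <- stats::runif(1, r, phantom$size_x - r)
    cy <- stats::runif(1, r, phantom$size_y - r)
    cz <- stats::runif(1, r, phantom$size_z - r)
    mu_t <- phantom$background$mu_a * stats::runif(1, contrast_range[1],
                                                   contrast_range[2])
    tumor_spec(cx, cy, cz, r, mu_t, phantom = phantom)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Parallel-plate source-detector layout
#'
#' Sources form a regular grid on the `z = 0` plate and detectors a regular
#' grid on the `z = size_z` plate, both inset by `margin` from the slab edges.
#' Counts are factorized into near-square grids with the longer grid axis
#' along x; the default 48 sources and 54 detectors give an 8 x 6 source grid,
#' a 9 x 6 detector grid and 2592 transmission channels.
#'
#' @param phantom a `slab_phantom`.
#' @param n_sources,n_detectors optode counts (default 48 and 54).
#' @param margin inset from the slab edge, mm.
#' @return an object of class `sd_layout` with `source_positions` and
#'   `detector_positions` matrices (`n x 3`, mm).
#' @examples
#' lay <- make_layout(make_slab_phantom())
#' nrow(lay$source_positions) * nrow(lay$detector_positions)  # 2592 channels
#' @export
make_layout <- function(phantom, n_sources = 48L, n_detectors = 54L,
                        margin = 10) {
  stopifnot(inherits(phantom, "slab_phantom"))
  grid_xy <- function(n, face_x, face_y) {
    divs <- which(n %% seq_len(n) == 0)
    pairs <- cbind(divs, n / divs)
    pairs <- pairs[pairs[, 1] >= pairs[, 2], , drop = FALSE]
    best <- pairs[which.min(pairs[, 1] / pairs[, 2]), ]
    nx <- best[1]; ny <- best[2]
    if (face_x - 2 * margin <= 0 || face_y - 2 * margin <= 0) {
      stop_dot("grid does not fit inside the face with margin %g mm", margin,
               class = "dot_layout_error")
    }
    xs <- if (nx == 1) face_x / 2 else seq(margin, face_x - margin, length.out = nx)
    ys <- if (ny == 1) face_y / 2 else seq(margin, face_y - margin, length.out = ny)
    as.matrix(expand.grid(x = xs, y = ys))
  }
  src <- grid_xy(as.integer(n_sources), phantom$size_x, phantom$size_y)
  det <- grid_xy(as.integer(n_detectors), phantom$size_x, phantom$size_y)
  structure(
    list(
      source_positions = cbind(src, z = 0),
      detector_positions = cbind(det, z = phantom$size_z)
    ),
    class = "sd_layout"
  )
}

#' @export
print.sd_layout <- function(x, ...) {
  cat(sprintf("<sd_layout> %d sources (z = 0), %d detectors (z = %.1f), %d channels\n",
              nrow(x$source_positions), nrow(x$detector_positions),
              x$detector_positions[1, 3],
              nrow(x$source_positions) * nrow(x$detector_positions)))
  invisible(x)
}
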