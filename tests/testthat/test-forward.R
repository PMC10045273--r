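op_default <- optical_properties()

test_that("infinite-medium fluence matches the closed form and decays monotonically", {
  # frozen from an independent high-precision evaluation of
  # exp(-mu_eff r) / (4 pi D r) at mu_a = 0.01, mu_s' = 1.0, r = 10
  expect_equal(infinite_medium_fluence(optical_properties(0.01, 1.0), 10),
               4.22922617929814e-3, tolerance = 1e-12)
  r <- seq(5, 150, by = 5)
  phi <- infinite_medium_fluence(op_default, r)
  expect_true(all(diff(phi) < 0))
  expect_error(infinite_medium_fluence(op_default, 0),
               class = "dot_singularity_error")
})

test_that("slab Green's function is reciprocal and converges with image pairs", {
  set.seed(4)
  for (i in 1:20) {
    a <- c(runif(1, 0, 220), runif(1, 0, 100), runif(1, 0, 23.7))
    b <- c(runif(1, 0, 220), runif(1, 0, 100), runif(1, 0, 23.7))
    if (all(a == b)) next
    f1 <- slab_fluence(op_default, 23.7, a, b)
    f2 <- slab_fluence(op_default, 23.7, b, a)
    expect_lt(abs(f1 - f2) / abs(f1), 1e-12)
    expect_gt(f1, 0)
  }
  a <- c(30, 40, 2); b <- c(100, 60, 21)
  f7 <- slab_fluence(op_default, 23.7, a, b, n_pairs = 7)
  f15 <- slab_fluence(op_default, 23.7, a, b, n_pairs = 15)
  expect_lt(abs(f7 - f15) / abs(f15), 1e-6)
})

test_that("slab solution approaches the infinite-medium form in a thick slab", {
  a <- c(100, 50, 100)
  b <- cbind(c(110, 50, 100), c(100, 58, 95), c(103, 47, 108))
  for (j in 1:3) {
    slab <- slab_fluence(op_default, 200, a, b[, j], n_pairs = 15)
    inf <- infinite_medium_fluence(op_default, sqrt(sum((a - b[, j])^2)))
    expect_lt(abs(slab - inf) / inf, 1e-3)
  }
})

test_that("Born perturbation vanishes at zero contrast and dims light at positive contrast", {
  ph <- tiny_phantom()
  null_tumor <- tumor_spec(110, 50, 12, 5, ph$background$mu_a + 1e-15)
  null_tumor$mu_a_tumor <- ph$background$mu_a  # exactly zero contrast
  expect_identical(
    born_perturbation(op_default, null_tumor, c(60, 50, 1), c(150, 50, 23), 23.7),
    0)
  tum <- tumor_spec(110, 50, 12, 6, 0.015, ph)
  for (s in list(c(30, 30, 1), c(110, 50, 1), c(180, 80, 1))) {
    for (d in list(c(110, 50, 23), c(60, 70, 23))) {
      expect_lt(born_perturbation(op_default, tum, s, d, 23.7, seed = 3), 0)
    }
  }
  shallow <- tumor_spec(110, 50, 3, 5, 0.015)
  expect_error(born_perturbation(op_default, shallow, c(0, 0, 1),
                                 c(110, 50, 23), 23.7),
               class = "dot_geometry_error")
})

test_that("Born quadrature is converged at the default node count", {
  tum <- tumor_spec(110, 50, 12, 2, 0.015)
  p500 <- born_perturbation(op_default, tum, c(100, 45, 1), c(120, 55, 23.7),
                            23.7, n_nodes = 500, seed = 1)
  p5000 <- born_perturbation(op_default, tum, c(100, 45, 1), c(120, 55, 23.7),
                             23.7, n_nodes = 5000, seed = 2)
  expect_lt(abs(p500 - p5000) / abs(p5000), 0.01)
})

test_that("simulated measurements respect symmetry, locality and determinism", {
  ph <- tiny_phantom()  # homogeneous
  lay <- tiny_layout(ph)
  bg <- simulate_measurement(ph, NULL, lay)
  expect_true(all(bg$readings > 0))
  # translation symmetry: co-axial channels (source directly under detector)
  # in a 4 x 3 / 4 x 3 grid layout all share the same geometry
  co <- which(apply(lay$source_positions[, 1:2], 1, paste, collapse = "_") %in%
                apply(lay$detector_positions[, 1:2], 1, paste, collapse = "_"))
  sgrid <- lay$source_positions
  dgrid <- lay$detector_positions
  same <- outer(seq_len(nrow(sgrid)), seq_len(nrow(dgrid)), Vectorize(
    function(i, j) all(sgrid[i, 1:2] == dgrid[j, 1:2])))
  vals <- matrix(bg$readings, nrow(sgrid), nrow(dgrid))[same]
  expect_gt(length(vals), 2)
  expect_lt(diff(range(vals)) / mean(vals), 1e-9)

  # locality of the tumor shadow, checked by exhaustive channel scan:
  # among the equal-length co-axial channels, the one whose chord passes
  # nearest the tumor center dims the most, and the globally most-dimmed
  # channel has a chord-to-center distance in the lowest decile (oblique
  # long chords can pass close yet carry little of the detected light)
  tum <- tumor_spec(120, 40, 11, 6, 0.018, ph)
  ms <- simulate_measurement(ph, tum, lay, seed = 9)
  frac <- matrix(ms$readings / bg$readings, nrow(sgrid), nrow(dgrid))
  co <- which(same, arr.ind = TRUE)
  co_frac <- frac[co]
  co_dist <- sqrt((sgrid[co[, 1], 1] - tum$center_x)^2 +
                    (sgrid[co[, 1], 2] - tum$center_y)^2)
  expect_equal(which.min(co_frac), which.min(co_dist))
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- pmin(pmax(sum((p - a) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  ctr <- c(tum$center_x, tum$center_y, tum$center_z)
  dists <- outer(seq_len(nrow(sgrid)), seq_len(nrow(dgrid)), Vectorize(
    function(i, j) seg_dist(ctr, sgrid[i, ], dgrid[j, ])))
  expect_lte(mean(dists <= dists[which.min(frac)]), 0.1)

  # deterministic forward model
  ms2 <- simulate_measurement(ph, tum, lay, seed = 9)
  expect_identical(ms$readings, ms2$readings)
})

test_that("stronger or larger absorbers never brighten any channel", {
  ph <- tiny_phantom()
  lay <- tiny_layout(ph, 6L, 6L)
  prev <- NULL
  for (r in c(3, 5, 7, 9)) {
    tum <- tumor_spec(110, 50, 11.85, r, 0.015, ph)
    ms <- simulate_measurement(ph, tum, lay, seed = 21)
    if (!is.null(prev)) expect_true(all(ms$readings <= prev + 1e-15))
    prev <- ms$readings
  }
  prev <- NULL
  for (mu in c(0.008, 0.011, 0.014, 0.017)) {
    tum <- tumor_spec(110, 50, 12, 5, mu, ph)
    ms <- simulate_measurement(ph, tum, lay, seed = 22)
    if (!is.null(prev)) expect_true(all(ms$readings <= prev + 1e-15))
    prev <- ms$readings
  }
})

test_that("measurement noise is multiplicative Gaussian at the stated level", {
  m <- structure(list(readings = matrix(1, 1, 1e6),
                      channel_index = NULL, noise_level = 0),
                 class = "measurement_set")
  expect_identical(add_noise(m, level = 0), m)
  noisy <- add_noise(m, level = 0.02, seed = 5)
  eps <- noisy$readings - 1
  expect_lt(abs(sd(eps) - 0.02) / 0.02, 0.01)
  expect_lt(abs(mean(eps)), 1e-4)
  expect_true(all(noisy$readings > 0))
  expect_identical(add_noise(m, 0.02, seed = 5)$readings, noisy$readings)
  expect_error(add_noise(m, level = -0.1), class = "dot_parameter_error")
})
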