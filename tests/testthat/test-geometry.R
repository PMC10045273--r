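test_that("slab phantom carries the compressed-breast dimensions and validates input", {
  ph <- make_slab_phantom(220.8, 102.9, 23.7, heterogeneity_amplitude = 0,
                          seed = 1)
  expect_equal(c(ph$size_x, ph$size_y, ph$size_z), c(220.8, 102.9, 23.7))
  expect_error(make_slab_phantom(size_x = -1), class = "dot_dimension_error")
  expect_error(make_slab_phantom(heterogeneity_amplitude = 0.7),
               class = "dot_dimension_error")
})

test_that("heterogeneity field is bounded, seeded, and absent in the homogeneous limit", {
  ph0 <- make_slab_phantom(heterogeneity_amplitude = 0)
  pts <- cbind(runif(50, 0, 220), runif(50, 0, 100), runif(50, 0, 23))
  expect_equal(heterogeneity_field(ph0, pts), rep(1, 50))

  ph1 <- make_slab_phantom(heterogeneity_amplitude = 0.1, seed = 42)
  ph2 <- make_slab_phantom(heterogeneity_amplitude = 0.1, seed = 42)
  expect_identical(heterogeneity_field(ph1, pts), heterogeneity_field(ph2, pts))
  expect_true(all(abs(heterogeneity_field(ph1, pts) - 1) <= 0.1))
  ph3 <- make_slab_phantom(heterogeneity_amplitude = 0.1, seed = 43)
  expect_false(identical(heterogeneity_field(ph1, pts),
                         heterogeneity_field(ph3, pts)))
})

test_that("sampled tumors respect the radius law and always fit the slab", {
  ph <- tiny_phantom()
  r_max <- min(15, ph$size_z / 2)
  draws <- t(vapply(seq_len(10000), function(i) {
    tum <- sample_tumor(ph, seed = i)
    c(tum$center_x, tum$center_y, tum$center_z, tum$radius, tum$mu_a_tumor)
  }, numeric(5)))
  r <- draws[, 4]
  expect_true(all(r >= 2 & r <= 15))
  # exact feasibility: distance from center to every face >= radius
  expect_true(all(draws[, 1] >= r & draws[, 1] <= ph$size_x - r))
  expect_true(all(draws[, 2] >= r & draws[, 2] <= ph$size_y - r))
  expect_true(all(draws[, 3] >= r & draws[, 3] <= ph$size_z - r))
  # tumor contrast in the configured range
  expect_true(all(draws[, 5] >= 2 * ph$background$mu_a - 1e-12 &
                    draws[, 5] <= 4 * ph$background$mu_a + 1e-12))
  # radii are uniform over the feasible range
  ks <- suppressWarnings(ks.test(r, "punif", 2, r_max))
  expect_gt(ks$p.value, 0.01)
  # seeded determinism
  expect_identical(sample_tumor(ph, seed = 7), sample_tumor(ph, seed = 7))
  thin <- make_slab_phantom(size_z = 3, heterogeneity_amplitude = 0)
  expect_error(sample_tumor(thin), class = "dot_geometry_error")
})

test_that("source-detector layout forms the stated plate grids", {
  ph <- tiny_phantom()
  lay <- make_layout(ph, 48, 54, margin = 10)
  expect_equal(nrow(lay$source_positions), 48)
  expect_equal(nrow(lay$detector_positions), 54)
  expect_equal(nrow(lay$source_positions) * nrow(lay$detector_positions), 2592)
  expect_true(all(lay$source_positions[, 3] == 0))
  expect_true(all(lay$detector_positions[, 3] == 23.7))
  # positions unique and interior
  expect_equal(nrow(unique(lay$source_positions)), 48)
  expect_true(all(lay$source_positions[, 1] > 0 &
                    lay$source_positions[, 1] < ph$size_x))
  # plate centroids coincide in (x, y)
  expect_lt(max(abs(colMeans(lay$source_positions[, 1:2]) -
                      colMeans(lay$detector_positions[, 1:2]))), 1e-9)
  # degenerate single-channel layout
  lay1 <- make_layout(ph, 1, 1, margin = 5)
  expect_equal(nrow(lay1$source_positions), 1)
  expect_equal(lay1$source_positions[1, 1:2],
               lay1$detector_positions[1, 1:2], ignore_attr = TRUE)
  expect_error(make_layout(ph, 48, 54, margin = 60),
               class = "dot_layout_error")
})
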