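test_that("affine fields carry exact closed-form Jacobians", {
  g <- small_grid()
  f0 <- make_affine_field(matrix(0, 3, 3), c(0, 0, 0), g)
  expect_equal(max(abs(f0$vectors)), 0)
  expect_equal(unique(as.vector(jacobian_truth(f0)$values)), 1)

  f_exp <- make_affine_field(diag(3) * 0.1, geom = g)
  expect_equal(unique(as.vector(jacobian_truth(f_exp)$values)), 1.1^3)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  f_rot <- make_affine_field(R - diag(3), geom = g)
  expect_equal(unique(as.vector(jacobian_truth(f_rot)$values)), 1, tolerance = 1e-12)
})

test_that("affine fields are exactly linear: second finite differences vanish", {
  g <- small_grid()
  set.seed(11)
  f <- make_affine_field(matrix(rnorm(9, sd = 0.05), 3, 3), rnorm(3), g)
  for (c_i in 1:3) {
    u <- f$vectors[, , , c_i]
    d2 <- u[3:10, , ] - 2 * u[2:9, , ] + u[1:8, , ]
    expect_lt(max(abs(d2)), 1e-10)
  }
})

test_that("axial sinusoid has the stated Jacobian range and folding guard", {
  g <- grid_geometry(c(16, 16, 200), c(1.5, 1.5, 1.0))
  f <- make_axial_sinusoid_field(5, 0.05, "z", g)
  truth <- jacobian_truth(f)$values
  # 200 mm of z at k = 0.05/mm covers > 1 period, so both extremes are hit
  expect_equal(max(truth), 1.25, tolerance = 1e-3)
  expect_equal(min(truth), 0.75, tolerance = 1e-3)
  expect_equal(max(abs(f$vectors[, , , 1:2])), 0)

  f0 <- make_axial_sinusoid_field(0, 0.05, "z", g)
  expect_equal(max(abs(f0$vectors)), 0)
  expect_equal(unique(as.vector(jacobian_truth(f0)$values)), 1)

  expect_error(make_axial_sinusoid_field(24, 0.05, "z", g), "fold")
})

test_that("sphere masks voxelize to the analytic volume within 2%", {
  g <- grid_geometry(c(40, 40, 40), c(1, 1, 1))
  m <- make_sphere_mask(c(19.5, 19.5, 19.5), 10, g)
  expect_lt(abs(sum(m$occupancy) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  expect_error(make_sphere_mask(c(500, 500, 500), 10, g), "empty")
  expect_error(make_sphere_mask(c(19.5, 19.5, 19.5), 0.5, g), "radius")
})

test_that("disjoint phantom spheres give DICE zero", {
  g <- default_grid()
  a <- make_sphere_mask(c(25, 48, 60), 12, g, "a")
  b <- make_sphere_mask(c(70, 48, 60), 12, g, "b")
  expect_equal(sum(a$occupancy & b$occupancy), 0)
  expect_equal(dice(a, b), 0)
})

test_that("fold injection is compactly supported and negative at the core", {
  g <- default_grid()
  base <- make_affine_field(diag(3) * 0.05, geom = g)
  centre <- c(48, 48, 60)
  folded <- inject_fold(base, centre, radius = 12, strength = 2)
  expect_equal(attr(folded, "fold_center_jacobian"), (1 - 2)^3)

  co <- dvfqa:::coord_arrays(g)
  r <- sqrt((co$x - centre[1])^2 + (co$y - centre[2])^2 + (co$z - centre[3])^2)
  outside <- r > 12 + 2 * max(g$spacing)
  for (c_i in 1:3) {
    expect_identical(folded$vectors[, , , c_i][outside],
                     base$vectors[, , , c_i][outside])
  }
  j <- jacobian_map(folded)
  inside <- r <= 12
  expect_lt(min(j$values[inside]), 0)

  # continuity: vanishing strength leaves the field unchanged
  eps_fold <- inject_fold(base, centre, radius = 12, strength = 1e-12)
  expect_lt(max(abs(eps_fold$vectors - base$vectors)), 1e-9)
  expect_error(inject_fold(base, c(500, 0, 0), 12, 2), "outside")
  expect_error(inject_fold(base, centre, 2, 2), "3 voxels")
})

test_that("cohort generation is a pure function of (n, seed, discrepancy)", {
  c1 <- make_synthetic_cohort(3, 123, 5)
  c2 <- make_synthetic_cohort(3, 123, 5)
  expect_identical(c1[[2]]$field_a$vectors, c2[[2]]$field_a$vectors)
  expect_identical(c1[[3]]$field_b$vectors, c2[[3]]$field_b$vectors)
  expect_identical(c1[[1]]$truth$volume_ratio, c2[[1]]$truth$volume_ratio)
  c3 <- make_synthetic_cohort(3, 124, 5)
  expect_false(identical(c1[[1]]$field_a$vectors, c3[[1]]$field_a$vectors))
  expect_error(make_synthetic_cohort(1, 1, 0), "n_patients")
})

test_that("cohort truth Jacobian matches the generated field", {
  co <- make_synthetic_cohort(2, 99, 0)
  for (case in co) {
    j <- jacobian_map(case$field_a)
    err <- max(abs(interior(j$values) - interior(case$truth$jacobian_a$values)))
    expect_lt(err, 2e-3)
    expect_true(all(is.finite(case$truth$jacobian_a$values)))
    expect_true(all(case$truth$jacobian_a$values > 0))
  }
})

test_that("zero discrepancy duplicates field_a; 10 mm peaks within [9, 10] mm", {
  co0 <- make_synthetic_cohort(2, 7, 0)
  expect_identical(co0[[1]]$field_a$vectors, co0[[1]]$field_b$vectors)
  expect_equal(max(co0[[1]]$truth$sd_mm$values), 0)

  co10 <- make_synthetic_cohort(2, 7, 10)
  for (case in co10) {
    d <- case$field_b$vectors - case$field_a$vectors
    true_sd <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
    expect_equal(max(abs(true_sd - case$truth$sd_mm$values)), 0, tolerance = 1e-9)
    expect_gte(max(true_sd), 9)
    expect_lte(max(true_sd), 10 + 1e-9)
    expect_gte(min(true_sd), 9 - 1e-9)  # near-uniform magnitude by design
  }
})
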