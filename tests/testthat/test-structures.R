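test_that("an axis-aligned 10x10 mm square rasterizes to 100 voxels", {
  g <- grid_geometry(c(20, 20, 3), c(1, 1, 1), c(0.5, 0.5, 0))
  sq <- list(list(slice = 2,
                  vertices = rbind(c(2, 2), c(12, 2), c(12, 12), c(2, 12))))
  m <- rasterize_contours(sq, g, "square")
  expect_equal(sum(m$occupancy), 100L)
  expect_equal(sum(m$occupancy[, , 2]), 100L)
  expect_equal(sum(m$occupancy[, , c(1, 3)]), 0L)
})

test_that("rasterization is orientation-free and rejects degenerate polygons", {
  g <- grid_geometry(c(20, 20, 2), c(1, 1, 1))
  v <- rbind(c(3, 4), c(14, 3), c(16, 12), c(8, 16), c(2, 11))
  m_ccw <- rasterize_contours(list(list(slice = 1, vertices = v)), g)
  m_cw <- rasterize_contours(list(list(slice = 1, vertices = v[nrow(v):1, ])), g)
  expect_identical(m_ccw$occupancy, m_cw$occupancy)
  expect_error(rasterize_contours(list(list(slice = 1, vertices = v[1:2, ])), g),
               "degenerate")
  expect_error(rasterize_contours(list(), g), "no contours")
  expect_error(rasterize_contours(list(list(slice = 9, vertices = v)), g),
               "slice")
})

test_that("rasterization matches an independent winding-parity oracle", {
  g <- grid_geometry(c(25, 25, 2), c(1.2, 0.9, 1), c(0, 0, 0))
  set.seed(21)
  for (rep in 1:5) {
    # star-shaped random polygon: strictly ordered angles avoid self-crossing
    n_v <- sample(4:9, 1)
    ang <- sort(runif(n_v, 0, 2 * pi))
    rad <- runif(n_v, 3, 11)
    v <- cbind(12 + rad * cos(ang), 10 + rad * sin(ang))
    m <- rasterize_contours(list(list(slice = 1, vertices = v)), g)
    xs <- g$origin[1] + (seq_len(25) - 1) * 1.2
    ys <- g$origin[2] + (seq_len(25) - 1) * 0.9
    pts <- expand.grid(x = xs, y = ys)
    oracle <- oracle_point_in_polygon(pts$x, pts$y, v[, 1], v[, 2])
    expect_identical(as.vector(m$occupancy[, , 1]), oracle)
  }
})

test_that("even-odd rule carves holes from nested contours", {
  g <- grid_geometry(c(30, 30, 2), c(1, 1, 1), c(0.5, 0.5, 0))
  outer <- rbind(c(2, 2), c(25, 2), c(25, 25), c(2, 25))
  inner <- rbind(c(10, 10), c(18, 10), c(18, 18), c(10, 18))
  m <- rasterize_contours(list(list(slice = 1, vertices = outer),
                               list(slice = 1, vertices = inner)), g)
  expect_equal(sum(m$occupancy), 23L * 23L - 8L * 8L)
})

test_that("warping with the zero field is the identity on masks", {
  g <- small_grid()
  m <- make_sphere_mask(c(2, 8, 17), 4.5, g)
  f0 <- displacement_field(g, array(0, dim = c(g$dims, 3)))
  expect_identical(warp_mask(m, f0)$occupancy, m$occupancy)
})

test_that("constant displacement shifts a mask by minus the displacement", {
  g <- grid_geometry(c(20, 18, 16), c(1.5, 1.5, 2.5))
  m <- make_sphere_mask(c(15, 13.5, 20), 6, g)
  u <- array(0, dim = c(g$dims, 3))
  u[, , , 1] <- 2 * g$spacing[1]  # +2 voxels along x
  shifted <- warp_mask(m, displacement_field(g, u))
  # pull-back: output voxel i is set iff input voxel i+2 was set
  expect_identical(shifted$occupancy[1:18, , ], m$occupancy[3:20, , ])
  expect_true(all(!shifted$occupancy[19:20, , ]))
  expect_equal(sum(shifted$occupancy), sum(m$occupancy))  # away from borders

  far <- displacement_field(g, array(1000, dim = c(g$dims, 3)))
  expect_equal(sum(warp_mask(m, far)$occupancy), 0L)
})

test_that("DICE implements 2|A.B|/(|A|+|B|) with its boundary identities", {
  g <- small_grid()
  m <- make_sphere_mask(c(2, 8, 17), 4.5, g)
  expect_equal(dice(m, m), 1)

  occ_a <- array(FALSE, dim = g$dims); occ_a[2:3, 2, 2] <- TRUE
  occ_b <- array(FALSE, dim = g$dims); occ_b[2, 2, 2] <- TRUE
  expect_equal(dice(structure_mask(g, occ_a), structure_mask(g, occ_b)), 2 / 3)
  expect_equal(dice(structure_mask(g, occ_b), structure_mask(g, occ_a)), 2 / 3)

  empty <- structure_mask(g, array(FALSE, dim = g$dims))
  expect_error(dice(empty, empty), "empty")
})

test_that("DICE decreases monotonically as nested spheres shrink", {
  g <- default_grid()
  ref <- make_sphere_mask(c(48, 48, 60), 16, g)
  d <- vapply(c(16, 13, 10, 7), function(r)
    dice(make_sphere_mask(c(48, 48, 60), r, g), ref), numeric(1))
  expect_equal(d[1], 1)
  expect_true(all(diff(d) < 0))
})

test_that("contour propagation through the true field improves DICE", {
  g <- default_grid()
  target <- make_sphere_mask(c(42, 48, 55), 14, g, "organ_exhale")
  shift <- c(6, -3, 10)  # whole voxels on the (1.5, 1.5, 2.5) mm lattice
  moving <- make_sphere_mask(c(42, 48, 55) + shift, 14, g, "organ_inhale")
  field <- displacement_field(g, sweep(array(0, dim = c(g$dims, 3)), 4, shift, `+`))
  d_orig <- dice(moving, target)
  d_def <- dice(warp_mask(moving, field), target)
  expect_gt(d_def, d_orig)
  expect_equal(d_def, 1)  # exact translation is recovered exactly
})

test_that("structure sampling carries exact voxel-volume weights", {
  g <- grid_geometry(c(20, 18, 16), c(1.5, 1.5, 2.5))
  m <- make_sphere_mask(c(15, 13.5, 20), 8, g)
  s_const <- sample_structure(scalar_volume(g, array(1.331, dim = g$dims)), m)
  expect_true(all(s_const$value == 1.331))
  expect_equal(sum(s_const$weight), sum(m$occupancy) * 5.625)
  expect_equal(attr(s_const, "total_volume"), sum(m$occupancy) * 5.625)
  expect_identical(attr(s_const, "label"), m$label)

  occ <- array(FALSE, dim = g$dims)
  occ[sample(prod(g$dims), 1000)] <- TRUE
  m1000 <- structure_mask(g, occ)
  s <- sample_structure(scalar_volume(g, array(0, dim = g$dims)), m1000)
  expect_equal(attr(s, "total_volume"), 5625)

  # samples read the map at the right voxels
  vals <- array(rnorm(prod(g$dims)), dim = g$dims)
  s2 <- sample_structure(scalar_volume(g, vals), m)
  expect_identical(s2$value, as.vector(vals[m$occupancy]))

  empty <- structure_mask(g, array(FALSE, dim = g$dims))
  expect_error(sample_structure(scalar_volume(g, vals), empty), "empty")
})

test_that("grid-boundary exclusion strips exactly the outer shell", {
  g <- small_grid()
  full <- structure_mask(g, array(TRUE, dim = g$dims))
  inner <- exclude_grid_boundary(full)
  expect_equal(sum(inner$occupancy), prod(g$dims - 2))
  expect_true(all(!boundary_shell_values(inner$occupancy)))
})
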