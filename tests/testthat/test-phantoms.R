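# Synthetic phantom generators: occupancy against brute-force membership
# oracles, Betti ground truth against the cubical oracle, sampling
# reproducibility and noise calibration.

test_that("cylinder occupancy matches the brute-force distance oracle", {
  ph <- make_cylinder(3, 20)
  # brute force: every lattice cell within in-plane distance 3 of the axis
  ctr <- ph$centerline[[1]]
  cx <- ctr[1, 1]; cy <- ctr[1, 2]
  expected <- 0L
  for (i in 1:(2 * cx)) for (j in 1:(2 * cy)) for (k in 1:20)
    if ((i - cx)^2 + (j - cy)^2 <= 9) expected <- expected + 1L
  expect_equal(nrow(ph$occupancy), expected)
  expect_equal(ph$betti, c(1L, 0L, 0L))
  expect_equal(oracle_betti_grid(phantom_grid(ph)), c(1L, 0L, 0L))
  # centerline cells lie inside the occupancy
  key <- paste(ph$occupancy[, 1], ph$occupancy[, 2], ph$occupancy[, 3])
  expect_true(all(paste(round(ctr[, 1]), round(ctr[, 2]), round(ctr[, 3]))
                  %in% key))
})

test_that("degenerate half-voxel cylinder is its own skeleton line", {
  ph <- make_cylinder(0.5, 5)
  expect_equal(nrow(ph$occupancy), 5L)
  rng <- apply(ph$occupancy, 2, function(v) length(unique(v)))
  expect_equal(sort(rng), c(1L, 1L, 5L))
  expect_error(make_cylinder(3, 2), "invalid")
  expect_error(make_cylinder(0.2, 5), "invalid")
})

test_that("elliptical tube: circle degenerate case, ER truth, slice oracle", {
  expect_equal(make_elliptical_tube(3, 3, 12)$occupancy,
               make_cylinder(3, 12)$occupancy)
  ph <- make_elliptical_tube(6, 2, 10)
  expect_true(all(ph$radius_profile[, 1] / ph$radius_profile[, 2] == 3))
  # per-cell ellipse membership oracle on one slice
  sl <- ph$occupancy[ph$occupancy[, 3] == 5L, 1:2, drop = FALSE]
  ca <- ph$centerline[[1]][1, 1]; cb <- ph$centerline[[1]][1, 2]
  manual <- NULL
  for (i in 1:(2 * ca)) for (j in 1:(2 * cb))
    if (((i - ca) / 6)^2 + ((j - cb) / 2)^2 <= 1) manual <- rbind(manual, c(i, j))
  expect_equal(sl[order(sl[, 1], sl[, 2]), ],
               manual[order(manual[, 1], manual[, 2]), ],
               ignore_attr = TRUE)
  expect_error(make_elliptical_tube(2, 6, 10), "major")
})

test_that("torus has one component, one loop, no cavity; ring is closed", {
  ph <- make_torus(8, 2)
  expect_equal(oracle_betti_grid(phantom_grid(ph)), c(1L, 1L, 0L))
  expect_equal(ph$betti, c(1L, 1L, 0L))
  ring <- round(ph$centerline[[1]])
  expect_true(max(abs(ring[1, ] - ring[nrow(ring), ])) <= 1)
  expect_error(make_torus(2, 2), "invalid")
})

test_that("two disjoint tori have b0 = 2 and b1 = 2 after union", {
  g <- two_phantom_grid(make_torus(6, 1.5), make_torus(6, 1.5))
  expect_equal(oracle_betti_grid(g), c(2L, 2L, 0L))
  expect_equal(betti_triple(topology_report(g)), c(2L, 2L, 0L))
})

test_that("Y junction: three centerline chains from one point, betti (1,0,0)", {
  ph <- make_y_junction(2, 2, c(35, 35))
  expect_length(ph$centerline, 3L)
  j1 <- ph$centerline$trunk[nrow(ph$centerline$trunk), ]
  expect_equal(unname(ph$centerline$branch1[1, ]), unname(j1))
  expect_equal(unname(ph$centerline$branch2[1, ]), unname(j1))
  expect_equal(oracle_betti_grid(phantom_grid(ph)), c(1L, 0L, 0L))
  expect_error(make_y_junction(2, 2, c(0, 35)), "invalid")
  expect_error(make_y_junction(0.5, 0.5), "invalid")
})

test_that("surface sampling is deterministic and hugs the surface", {
  ph <- make_cylinder(3, 12)
  sp <- sampling_spec(seed = 7L)
  c1 <- sample_surface_cloud(ph, sp)
  c2 <- sample_surface_cloud(ph, sp)
  expect_identical(c1$points, c2$points)
  # noise-free points lie within half a voxel diagonal of the boundary:
  # every point voxelises into a surface cell of the phantom
  g <- voxelize(c1, voxel_size = ph$voxel_size,
                origin = rep(-ph$voxel_size, 3))
  occ_keys <- paste(ph$occupancy[, 1], ph$occupancy[, 2], ph$occupancy[, 3])
  got <- occupied_indices(g) - 1L
  expect_true(all(paste(got[, 1], got[, 2], got[, 3]) %in% occ_keys))
})

test_that("Gaussian jitter has the requested standard deviation", {
  ph <- make_cylinder(4, 30)
  dens <- 100 / ph$voxel_size^2
  base <- sample_surface_cloud(ph, sampling_spec(dens, 0, seed = 11L))
  noisy <- sample_surface_cloud(ph, sampling_spec(dens, 0.5, seed = 11L))
  jit <- noisy$points - base$points
  expect_gt(nrow(jit), 1e5)
  sds <- apply(jit, 2, sd)
  expect_true(all(abs(sds / (0.5 * ph$voxel_size) - 1) < 0.02))
})

test_that("spherical-cap holes remove a surface patch", {
  ph <- make_cylinder(4, 20)
  hole <- list(center = c(1, 0, 0), angular_radius = 25)
  full <- sample_surface_cloud(ph, sampling_spec(seed = 3L))
  holed <- sample_surface_cloud(ph, sampling_spec(seed = 3L,
                                                  hole_specs = list(hole)))
  expect_lt(nrow(holed$points), nrow(full$points))
})

test_that("too-low density warns instead of failing", {
  ph <- make_cylinder(2, 6)
  expect_warning(
    sample_surface_cloud(ph, sampling_spec(points_per_unit_area = 3000,
                                           seed = 1L)),
    "density")
})

test_that("noise-free pipeline recovers at least 99% of phantom occupancy", {
  for (ph in list(make_cylinder(3, 15), make_elliptical_tube(5, 2, 12),
                  make_torus(7, 2), make_y_junction(2, 2, c(35, 35)))) {
    g <- prepare_phantom_run(ph, sigma_ratio = 0, seed = 5L)$grid
    # phantom cell centers must land in object cells of the processed grid
    idx <- ph$occupancy + 2L
    d <- dim(g$occ)
    ok <- idx[, 1] <= d[1] & idx[, 2] <= d[2] & idx[, 3] <= d[3]
    expect_gte(sum(g$occ[idx[ok, , drop = FALSE]]) / nrow(idx), 0.99)
  }
})

test_that("phantoms serialize losslessly to text + JSON sidecar", {
  ph <- make_torus(6, 2)
  path <- file.path(tempdir(), "torus_phantom.txt")
  write_phantom(ph, path)
  back <- read_phantom(path)
  expect_equal(back$occupancy, ph$occupancy)
  expect_equal(back$betti, ph$betti)
  expect_equal(back$voxel_size, ph$voxel_size)
})
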