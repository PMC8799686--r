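# Voxelisation, neighbourhood primitives and connected components.

test_that("a single point yields exactly one object voxel containing it", {
  g <- voxelize(point_cloud(matrix(c(0.123, 0.456, 0.789), 1, 3)),
                voxel_size = 0.05)
  idx <- occupied_indices(g)
  expect_equal(nrow(idx), 1L)
  ctr <- voxel_centers(g, idx)
  expect_true(all(abs(ctr - c(0.123, 0.456, 0.789)) <= 0.025 + 1e-12))
})

test_that("octree depth 1 splits cube corners into 8 object voxels", {
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  g <- voxelize(point_cloud(corners * 0.999), depth = 1L)
  expect_equal(nrow(occupied_indices(g)), 8L)
  # bounding cube side = voxel_size * 2^depth
  expect_equal(g$voxel_size * 2^1, 0.999, tolerance = 1e-9)
  expect_warning(g7 <- voxelize(point_cloud(corners), depth = 7L),
                 "holes likely")
  expect_equal(g7$voxel_size * 2^7, 1, tolerance = 1e-9)
  expect_error(voxelize(point_cloud(corners)), "exactly one")
  expect_error(voxelize(point_cloud(corners[0, , drop = FALSE]),
                        voxel_size = 1), "empty")
})

test_that("voxelization is idempotent on voxel-center points", {
  ph <- make_torus(6, 2)
  g <- phantom_grid(ph)
  ctr <- voxel_centers(g)
  g2 <- voxelize(point_cloud(ctr), voxel_size = g$voxel_size,
                 origin = g$origin)
  idx1 <- occupied_indices(g)
  idx2 <- occupied_indices(g2)
  expect_equal(idx2, idx1)
})

test_that("neighbors counts, nesting and clipping", {
  g <- voxel_grid(array(TRUE, c(4, 4, 4)), 0.01)
  inner <- c(2L, 2L, 2L)
  expect_equal(nrow(neighbors(g, inner, 6)), 6L)
  expect_equal(nrow(neighbors(g, inner, 18)), 18L)
  expect_equal(nrow(neighbors(g, inner, 26)), 26L)
  corner <- c(1L, 1L, 1L)
  expect_equal(nrow(neighbors(g, corner, 6)), 3L)
  expect_equal(nrow(neighbors(g, corner, 26)), 7L)
  # nesting on every cell of a small grid
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    n6 <- neighbors(g, c(i, j, k), 6)
    n18 <- neighbors(g, c(i, j, k), 18)
    n26 <- neighbors(g, c(i, j, k), 26)
    k6 <- paste(n6[, 1], n6[, 2], n6[, 3])
    k18 <- paste(n18[, 1], n18[, 2], n18[, 3])
    k26 <- paste(n26[, 1], n26[, 2], n26[, 3])
    expect_true(all(k6 %in% k18) && all(k18 %in% k26))
  }
  expect_error(neighbors(g, c(0L, 1L, 1L)), "bounds")
  expect_error(neighbors(g, c(5L, 1L, 1L)), "bounds")
})

test_that("corner-touching voxels split under 6- but not 26-connectivity", {
  g <- voxel_grid(rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)), 0.01, dims = c(3, 3, 3))
  expect_length(connected_components(g, code = 6L), 2L)
  expect_length(connected_components(g, code = 26L), 1L)
  cube <- solid_box_grid(c(5L, 5L, 5L))
  comps <- connected_components(cube)
  expect_length(comps, 1L)
  expect_equal(nrow(comps[[1]]), 125L)
})

test_that("component partition matches a brute-force union-find oracle", {
  set.seed(99)
  dims <- c(10L, 10L, 10L)
  cells <- unique(cbind(sample(10, 200, TRUE), sample(10, 200, TRUE),
                        sample(10, 200, TRUE)))
  g <- voxel_grid(cells, 0.01, dims = dims)
  for (code in c(6L, 26L)) {
    comps <- connected_components(g, cells, code)
    oracle <- oracle_union_find(cells, code)
    sizes1 <- sort(vapply(comps, nrow, integer(1)))
    sizes2 <- sort(lengths(oracle))
    expect_equal(sizes1, sizes2)
    # identical partition, not just sizes: same member keys per component
    keyset <- function(rows) paste(sort(paste(rows[, 1], rows[, 2], rows[, 3])),
                                   collapse = ";")
    k1 <- sort(vapply(comps, keyset, ""))
    k2 <- sort(vapply(oracle, function(r) keyset(cells[r, , drop = FALSE]), ""))
    expect_equal(k1, k2)
  }
  # enumeration-order invariance
  perm <- sample(nrow(cells))
  comps_p <- connected_components(g, cells[perm, ], 26L)
  expect_equal(vapply(comps_p, nrow, integer(1)),
               vapply(connected_components(g, cells, 26L), nrow, integer(1)))
})

test_that("grids serialize to columnar text + JSON header and back", {
  g <- phantom_grid(make_cylinder(2, 8))
  p <- file.path(tempdir(), "grid_rt.txt")
  write_grid(g, p)
  back <- read_grid(p)
  expect_equal(occupied_indices(back), occupied_indices(g))
  expect_equal(back$voxel_size, g$voxel_size)
  expect_equal(dim(back$occ), dim(g$occ))
})
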