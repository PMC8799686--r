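# Assessment metrics: topology reports, centeredness, replication,
# rotational invariance, scalability reporting.

test_that("topology_report matches the Euler/cavity oracle on canonical solids", {
  cube <- solid_box_grid(c(5L, 5L, 5L))
  expect_equal(betti_triple(topology_report(cube)), c(1L, 0L, 0L))
  tor <- phantom_grid(make_torus(7, 2))
  tr <- topology_report(tor)
  expect_equal(betti_triple(tr), c(1L, 1L, 0L))
  expect_equal(tr$euler, oracle_euler(occupied_indices(tor)))
  expect_equal(tr$euler, 0L)                 # chi of a solid torus
  # hollow shell: one cavity, chi = 2
  A <- array(FALSE, c(7, 7, 7))
  A[2:6, 2:6, 2:6] <- TRUE
  A[3:5, 3:5, 3:5] <- FALSE
  shell <- voxel_grid(A, 0.01)
  sr <- topology_report(shell)
  expect_equal(betti_triple(sr), c(1L, 0L, 1L))
  expect_equal(sr$euler, 2L)
  expect_equal(betti_triple(topology_report(
    voxel_grid(array(FALSE, c(3, 3, 3)), 0.01))), c(0L, 0L, 0L))
})

test_that("centeredness bins at 0.5 and 1.5 voxel widths", {
  # skeleton equal to the centerline: all correct
  line <- cbind(4, 4, 1:10)
  rep0 <- centeredness(line, line)
  expect_equal(unname(rep0$fractions), c(1, 0, 0))
  # offset by exactly one voxel: all acceptable, none correct
  rep1 <- centeredness(sweep(line, 2, c(1, 0, 0), "+"), line)
  expect_equal(unname(rep1$fractions), c(0, 1, 0))
  expect_equal(sum(rep1$fractions), 1)
  # offset by two voxels: poor
  rep2 <- centeredness(sweep(line, 2, c(2, 0, 0), "+"), line)
  expect_equal(unname(rep2$fractions[["poor"]]), 1)
  empty <- centeredness(matrix(numeric(0), 0, 3), line)
  expect_length(empty$deviation, 0L)
})

test_that("cylinder pipeline output is >= 87% within 1.5 voxel widths", {
  ph <- make_cylinder(4, 30)
  s <- thin(prepare_phantom_run(ph, sigma_ratio = 0, seed = 2L)$grid)
  # centeredness() maps the skeleton back into phantom-lattice units via
  # the grid origin; the half-voxel lattice offset of the survey frame
  # costs at most sqrt(3)/2 widths, inside the acceptable bin
  cen <- centeredness(s, ph$centerline[[1]])
  expect_gte(cen$fractions[["correct"]] + cen$fractions[["acceptable"]], 0.87)
})

test_that("replication metrics are exact set arithmetic", {
  g <- phantom_grid(make_cylinder(3, 10))
  same <- replication_metrics(g, g)
  expect_equal(same$replicated_fraction, 1)
  expect_equal(same$correct_fraction, 1)
  # strict superset doubling occupancy: replicated 1, correct 0.5
  occ <- g$occ
  void <- which(!occ)
  set.seed(1)
  occ[sample(void, sum(occ))] <- TRUE
  sup <- grid_sup <- voxel_grid(occ, g$voxel_size, g$origin)
  m <- replication_metrics(g, sup)
  expect_equal(m$replicated_fraction, 1)
  expect_equal(m$correct_fraction, 0.5)
  # random half subset: replicated 0.5, correct 1
  idx <- occupied_indices(g)
  half <- idx[sample(nrow(idx), nrow(idx) / 2), ]
  subg <- voxel_grid(half, g$voxel_size, dims = dim(g$occ))
  m2 <- replication_metrics(g, subg)
  expect_equal(m2$replicated_fraction, 0.5)
  expect_equal(m2$correct_fraction, 1)
  # symmetry under swapping arguments
  m3 <- replication_metrics(subg, g)
  expect_equal(m3$replicated_fraction, m2$correct_fraction)
  expect_equal(m3$correct_fraction, m2$replicated_fraction)
  expect_error(replication_metrics(g, solid_box_grid(c(2L, 2L, 2L))),
               "dims")
})

test_that("three-way replication labelling exports as PLY", {
  g <- phantom_grid(make_cylinder(2, 6))
  rec <- reconstruct_circular(thin(g), 4)
  rep <- replication_metrics(g, rec)
  p <- tempfile(fileext = ".ply")
  export_replication_ply(rep, g, p)
  cl <- read_cloud(p)
  expect_equal(nrow(cl$points),
               nrow(rep$labels$common) + nrow(rep$labels$redundant) +
                 nrow(rep$labels$missing))
})

test_that("rotational invariance: symmetric phantom overlaps fully", {
  g <- phantom_grid(make_cylinder(3, 14))
  ri <- rotational_invariance(g, "z")
  expect_equal(ri$overlap_fraction, 1)
  expect_true(ri$topology_equal)
  expect_error(rotational_invariance(g, "diag"), "quarter")
})

test_that("rotational invariance on an asymmetric anastomotic loop stays within 2 voxels", {
  # two fused coplanar rings: an asymmetric closed structure with b1 = 2
  # and no free branch tips (tip erosion depth is direction-dependent, so
  # open-ended phantoms measure tip length, not centering)
  t1 <- make_torus(7, 2)
  o2 <- t1$occupancy
  o2[, 1] <- o2[, 1] + 9L
  occ <- unique(rbind(t1$occupancy, o2)) + 1L
  g <- voxel_grid(occ, 0.01, dims = apply(occ, 2, max) + 1L)
  expect_equal(betti_triple(g), c(1L, 2L, 0L))
  ri <- rotational_invariance(g, "z")
  expect_true(ri$topology_equal)
  expect_lte(ri$max_deviation, 2)
})

test_that("scalability report carries per-step timings and reduction", {
  ph <- make_cylinder(3, 16)
  cl <- sample_surface_cloud(ph, sampling_spec(seed = 9L))
  p <- tempfile(fileext = ".xyz")
  write_cloud(cl, p)
  cfg <- pipeline_config(input = p, voxel_size = ph$voxel_size)
  run <- run_pipeline(cfg)
  sc <- scalability_report(run)
  expect_true(all(c("read", "voxelize", "denoise", "fill_internal", "thin",
                    "segment", "reconstruct") %in% sc$steps$step))
  expect_true(all(is.finite(sc$steps$seconds)))
  expect_gt(sc$reduction_percent, 0)
  # skeleton CSV is smaller than the input cloud file
  sk <- tempfile(fileext = ".csv")
  write_skeleton(run$skeleton, sk)
  expect_lt(file.size(sk), file.size(p))
})
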