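# Sequential template thinning: deletion criteria, homotopy, exposure
# bookkeeping, curve-end protection and thinness.

test_that("is_deletable honours the four criteria", {
  # lone pair: x has one object neighbour, no candidate neighbours ->
  # (c)/(d) vacuous, (a)/(b) decide (both hold here)
  g <- voxel_grid(rbind(c(2L, 2L, 2L), c(3L, 2L, 2L)), 0.01, dims = c(5, 4, 4))
  expect_true(is_deletable(g, c(2L, 2L, 2L), rbind(c(2L, 2L, 2L))))
  # criterion (a): removal would split the neighbourhood into 2 components
  g2 <- voxel_grid(rbind(c(2L, 2L, 2L), c(1L, 1L, 2L), c(3L, 3L, 2L)),
                   0.01, dims = c(4, 4, 4))
  expect_false(is_deletable(g2, c(2L, 2L, 2L), rbind(c(2L, 2L, 2L))))
  # criterion (c): in a bare 2-voxel bar with both voxels candidates there
  # is no witness z, so neither end may go -- mutual deletion is blocked
  cand <- rbind(c(2L, 2L, 2L), c(3L, 2L, 2L))
  expect_false(is_deletable(g, c(2L, 2L, 2L), cand))
  expect_false(is_deletable(g, c(3L, 2L, 2L), cand))
  expect_error(is_deletable(g, c(2L, 2L, 2L), rbind(c(3L, 2L, 2L))),
               "contract violation")
})

test_that("single voxels and short bars survive thinning", {
  lone <- voxel_grid(rbind(c(2L, 2L, 2L)), 0.01, dims = c(3, 3, 3))
  s <- thin(lone)
  expect_equal(nrow(s$voxels), 1L)
  two <- voxel_grid(rbind(c(2L, 2L, 2L), c(3L, 2L, 2L)), 0.01,
                    dims = c(5, 4, 4))
  s2 <- thin(two)
  expect_gte(nrow(s2$voxels), 1L)           # at most one deleted
  expect_equal(betti_triple(s2$grid), c(1L, 0L, 0L))
})

test_that("curve ends of a 1-voxel-wide chain survive", {
  g <- chain_grid(10)
  s <- thin(g)
  expect_equal(nrow(s$voxels), 10L)
  expect_equal(s$grid$occ, g$occ, ignore_attr = TRUE)
})

test_that("a solid 5x5 bar thins to its centerline with I2 = 2", {
  g <- solid_box_grid(c(5L, 5L, 12L))
  s <- thin(g)
  v <- s$voxels
  expect_true(all(v$i == 4L & v$j == 4L))   # exact center column
  mid <- v[v$k %in% 5:9, ]
  expect_true(all(mid$I2 == 2L))
  expect_true(thinness_check(s))
})

test_that("exposure iterations are ordered and track local radius", {
  for (r in c(2, 3, 4)) {
    s <- thin(phantom_grid(make_cylinder(r, 24)))
    v <- s$voxels
    expect_true(all(v$I1 <= v$I2, na.rm = TRUE))
    expect_true(all(v$I2 <= v$I3, na.rm = TRUE))
    expect_true(all(v$I3 <= v$I4, na.rm = TRUE))
    mid <- v[v$k >= 10 & v$k <= 16, ]
    expect_true(all(mid$I2 == r))           # one cycle ~ one voxel shell
  }
})

test_that("occupancy strictly decreases every non-final cycle", {
  g <- phantom_grid(make_cylinder(3, 16))
  s <- thin(g, audit = TRUE)
  per_cycle <- table(s$audit$cycle)
  expect_equal(as.integer(names(per_cycle)), seq_along(per_cycle))
  expect_true(all(per_cycle > 0))
})

test_that("thinning preserves the Betti triple across the phantom suite", {
  suite <- list(cyl = phantom_grid(make_cylinder(4, 20)),
                ell = phantom_grid(make_elliptical_tube(6, 2, 16)),
                tor = phantom_grid(make_torus(8, 2)),
                y   = phantom_grid(make_y_junction(2, 2, c(35, 35))),
                tor2 = two_phantom_grid(make_torus(6, 1.5), make_torus(6, 1.5)))
  for (nm in names(suite)) {
    g <- suite[[nm]]
    s <- thin(g)
    expect_equal(betti_triple(s$grid), betti_triple(g), label = nm)
    expect_equal(oracle_betti(s$grid$occ), oracle_betti(g$occ), label = nm)
  }
})

test_that("the torus skeleton is a closed 1-voxel loop", {
  s <- thin(phantom_grid(make_torus(8, 2)))
  expect_equal(betti_triple(s$grid), c(1L, 1L, 0L))
  expect_true(thinness_check(s))
  roles <- classify_voxels(s)
  expect_false(any(roles == "end"))
})

test_that("every thinning deletion is a simple point at its moment of deletion", {
  # exhaustive audit replay on small grids against the independent
  # brute-force Betti oracle
  for (g in list(phantom_grid(make_cylinder(3, 8)),
                 phantom_grid(make_torus(2.5, 1.2)),
                 solid_box_grid(c(6L, 6L, 6L)))) {
    expect_lte(max(dim(g$occ)), 12L)
    s <- thin(g, audit = TRUE)
    A <- g$occ
    ref <- oracle_betti(A)
    for (r in seq_len(nrow(s$audit))) {
      A[s$audit$i[r], s$audit$j[r], s$audit$k[r]] <- FALSE
      now <- oracle_betti(A)
      expect_equal(now, ref,
                   label = sprintf("betti after deletion %d", r))
      ref <- now
    }
    expect_equal(sum(A), nrow(s$voxels))
  }
})

test_that("thinness: chains pass, double chains fail", {
  expect_true(thinness_check(chain_grid(8)))
  A <- array(FALSE, c(4, 3, 12))
  A[2:3, 2, 2:11] <- TRUE                   # 2x1 double chain
  expect_false(thinness_check(voxel_grid(A, 0.01)))
  bad <- attr(thinness_check(voxel_grid(A, 0.01)), "removable")
  expect_gt(nrow(bad), 0L)
})

test_that("phantom skeletons contain no removable voxels", {
  for (ph in list(make_cylinder(4, 20), make_elliptical_tube(6, 2, 16),
                  make_torus(8, 2), make_y_junction(2, 2, c(35, 35)))) {
    expect_true(thinness_check(thin(phantom_grid(ph))), label = ph$kind)
  }
})

test_that("tubular skeleton voxels keep at least four exposed faces", {
  for (ph in list(make_cylinder(4, 20), make_torus(8, 2))) {
    s <- thin(phantom_grid(ph))
    expect_true(all(s$voxels$exposed_faces >= 4L), label = ph$kind)
    expect_true(all(!is.na(s$voxels$I4)), label = ph$kind)
  }
})

test_that("straight cylinder skeleton stays within one voxel of the axis", {
  ph <- make_cylinder(4, 30)
  s <- thin(phantom_grid(ph))
  cen <- centeredness(s, ph)
  expect_gte(cen$fractions[["correct"]] + cen$fractions[["acceptable"]], 0.87)
})
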