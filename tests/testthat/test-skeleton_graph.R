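# Branch/joint segmentation of thinned skeletons.

test_that("a straight chain classifies as two ends and regular interior", {
  g <- chain_grid(9)
  roles <- classify_voxels(g)
  expect_equal(sum(roles == "end"), 2L)
  expect_equal(sum(roles == "regular"), 7L)
  expect_equal(sum(roles == "joint"), 0L)
})

test_that("a drawn closed loop is all regular", {
  # octagonal ring: every voxel has exactly two 26-neighbours
  ring <- rbind(c(4, 2), c(5, 2), c(6, 3), c(6, 4), c(5, 5), c(4, 5),
                c(3, 4), c(3, 3))
  g <- voxel_grid(cbind(ring, 2L), 0.01, dims = c(8, 7, 3))
  roles <- classify_voxels(g)
  expect_true(all(roles == "regular"))
  gr <- segment_branches(g)
  expect_length(gr$branches, 1L)
  expect_true(isTRUE(gr$branches[[1]]$loop))
  expect_equal(nrow(gr$nodes), 0L)
  expect_equal(gr$branches[[1]]$n_voxels, 8L)
})

test_that("isolated voxel warns and is labelled a curve end", {
  g <- voxel_grid(rbind(c(2L, 2L, 2L), c(5L, 5L, 5L), c(5L, 5L, 6L)),
                  0.01, dims = c(7, 7, 7))
  expect_warning(roles <- classify_voxels(g), "isolated")
  expect_equal(roles[1], "end")
})

test_that("joint clusters merge to the member nearest the centroid", {
  # single joint voxel is its own true joint
  j1 <- list(true = c(3L, 3L, 3L))
  A <- array(FALSE, c(7, 7, 7))
  A[3, 3, 2:4] <- TRUE; A[2, 3, 3] <- TRUE; A[4, 2, 2] <- TRUE
  # build an explicit Y: center (3,3,3) with three arms
  g <- voxel_grid(A, 0.01)
  roles <- classify_voxels(g)
  jm <- merge_joint_clusters(g, roles)
  expect_equal(nrow(jm$true_joints), 1L)
  expect_equal(jm$true_joints[1, ], c(3L, 3L, 3L))
  # 3-in-a-row collinear cluster: middle voxel wins
  sel <- rbind(c(3L, 3L, 2L), c(3L, 3L, 3L), c(3L, 3L, 4L))
  ctr <- colMeans(sel)
  d2 <- rowSums(sweep(sel, 2, ctr)^2)
  expect_equal(which.min(d2), 2L)
})

test_that("Y-junction skeleton segments into 3 branches, 1 joint, 3 ends", {
  s <- thin(phantom_grid(make_y_junction(2, 2, c(35, 35))))
  suppressMessages(gr <- segment_branches(s))
  expect_length(gr$branches, 3L)
  expect_equal(sum(gr$nodes$kind == "joint"), 1L)
  expect_equal(sum(gr$nodes$kind == "end"), 3L)
  # ownership partition: interiors + joint-cluster voxels + ends = all
  own <- sum(vapply(gr$branches, function(b) length(b$interior), integer(1))) +
    sum(gr$roles == "end") + sum(!is.na(gr$cluster_id))
  expect_equal(own, nrow(gr$voxels))
})

test_that("axis-aligned chain has metric length (n-1) * voxel_size", {
  g <- chain_grid(9, voxel_size = 0.02)
  gr <- segment_branches(thin(g))
  expect_length(gr$branches, 1L)
  expect_equal(gr$branches[[1]]$n_voxels, 9L)
  expect_equal(gr$branches[[1]]$length, 8 * 0.02, tolerance = 1e-12)
})

test_that("graph cycle rank equals skeleton b1", {
  for (ph in list(make_torus(8, 2), make_y_junction(2, 2, c(35, 35)))) {
    s <- thin(phantom_grid(ph))
    suppressMessages(gr <- segment_branches(s))
    v <- nrow(gr$nodes)
    realized <- Filter(function(b) isTRUE(b$loop) ||
                         (!is.na(b$from) && !is.na(b$to)), gr$branches)
    e <- length(realized)
    ncomp <- betti_triple(s$grid)[1]
    loops <- sum(vapply(gr$branches, function(b) isTRUE(b$loop), logical(1)))
    rank <- e - max(v, 1L * (loops > 0)) + ncomp + ifelse(v == 0, loops - 1, 0)
    # cycle rank of the realized multigraph (loops count 1 each)
    rank <- loops + (e - loops) - v + ncomp
    expect_equal(rank, betti_triple(s$grid)[2], label = ph$kind)
  }
})

test_that("graph exports round-trip (JSON) and preserve counts (GraphML, OBJ)", {
  s <- thin(phantom_grid(make_y_junction(2, 2, c(35, 35))))
  suppressMessages(gr <- segment_branches(s))
  pj <- tempfile(fileext = ".json")
  export_graph(gr, pj)
  back <- import_graph(pj)
  expect_equal(nrow(back$nodes), nrow(gr$nodes))
  expect_equal(length(back$branches), length(gr$branches))
  expect_equal(back$voxels, gr$voxels)
  for (b in seq_along(gr$branches)) {
    expect_equal(back$branches[[b]]$voxels, gr$branches[[b]]$voxels)
    expect_equal(back$branches[[b]]$length, gr$branches[[b]]$length)
  }
  pg <- tempfile(fileext = ".graphml")
  export_graph(gr, pg)
  ig <- igraph::read_graph(pg, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(gr$nodes))
  expect_equal(igraph::ecount(ig), 3L)
  po <- tempfile(fileext = ".obj")
  export_graph(gr, po)
  obj <- readLines(po)
  nverts <- sum(grepl("^v ", obj))
  total_branch_voxels <- sum(vapply(gr$branches, function(b) nrow(b$voxels),
                                    integer(1)))
  expect_equal(nverts, total_branch_voxels)
  expect_error(export_graph(gr, tempfile(fileext = ".xyz")), "unknown")
})
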