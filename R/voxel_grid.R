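# ---- voxel_grid class -------------------------------------------------------

#' Construct a voxel grid
#'
#' An axis-aligned occupancy lattice.  Cell `(i, j, k)` (1-based) spans the
#' half-open world box `origin + ((i,j,k) - 1) * voxel_size` to
#' `origin + (i,j,k) * voxel_size`; its center is
#' `origin + ((i,j,k) - 0.5) * voxel_size`.
#'
#' @param occupancy logical 3D array, or an n x 3 integer index matrix
#'   (with `dims` then required).
#' @param voxel_size edge length in metres.
#' @param origin world coordinate of the corner of cell `(1,1,1)`.
#' @param dims grid dimensions when `occupancy` is an index matrix.
#' @param depth informational octree depth, if known.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(occupancy, voxel_size, origin = c(0, 0, 0),
                       dims = NULL, depth = NA_integer_) {
  if (is.array(occupancy) && length(dim(occupancy)) == 3L) {
    occ <- occupancy
    storage.mode(occ) <- "logical"
  } else {
    if (is.null(dims)) stop("dims required when occupancy is an index matrix")
    idx <- idx_matrix(occupancy)
    if (nrow(idx) > 0L &&
        (any(idx < 1L) || any(idx[, 1] > dims[1]) ||
         any(idx[, 2] > dims[2]) || any(idx[, 3] > dims[3])))
      stop("occupied index outside grid dims")
    occ <- array(FALSE, dims)
    occ[lin_index(idx, dims)] <- TRUE
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a positive scalar")
  structure(
    list(occ = occ, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), depth = depth),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$occ)
  cat(sprintf("<voxel_grid> %d x %d x %d cells, %d occupied, voxel %.4g m\n",
              d[1], d[2], d[3], sum(x$occ), x$voxel_size))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$occ)

#' Occupied cell indices of a grid
#'
#' @param grid a `voxel_grid`.
#' @return integer matrix (n x 3) of 1-based indices.
#' @export
occupied_indices <- function(grid) {
  w <- which(grid$occ, arr.ind = TRUE)
  dimnames(w) <- NULL
  storage.mode(w) <- "integer"
  w
}

#' World coordinates of voxel centers
#'
#' @param grid a `voxel_grid`.
#' @param idx n x 3 index matrix (possibly real-valued lattice positions);
#'   defaults to all occupied cells.
#' @return n x 3 numeric matrix in metres.
#' @export
voxel_centers <- function(grid, idx = occupied_indices(grid)) {
  idx <- as.matrix(idx)
  sweep(sweep(idx, 2, 0.5) * grid$voxel_size, 2, grid$origin, "+")
}

grid_replace_occ <- function(grid, occ) {
  grid$occ <- occ
  grid
}

#' Voxelize a point cloud
#'
#' Builds an occupancy lattice from a cloud.  A cell is an object voxel iff
#' at least one point falls in its half-open box.  When `depth` is given the
#' bounding cube of the cloud is split octree-style, `2^depth` cells per
#' axis, so `voxel_size = side / 2^depth`.  The grid is padded by one void
#' layer on every face so that an external void always exists for the
#' internal-space flood fill and template matching at the data boundary is
#' well defined.
#'
#' @param cloud a `point_cloud` or an n x 3 matrix of coordinates (metres).
#' @param depth octree depth (mutually exclusive with `voxel_size`).
#' @param voxel_size voxel edge length in metres (mutually exclusive with
#'   `depth`).
#' @param origin optional world coordinate for the corner of cell `(1,1,1)`;
#'   when supplied the lattice is anchored there (used to align grids with
#'   phantom lattices).  Otherwise the origin is the cloud minimum minus one
#'   voxel of padding.
#' @return a `voxel_grid`.
#' @export
voxelize <- function(cloud, depth = NULL, voxel_size = NULL, origin = NULL) {
  pts <- as_point_matrix(cloud)
  if (nrow(pts) == 0L) stop("empty cloud: nothing to voxelize")
  if (is.null(depth) == is.null(voxel_size))
    stop("give exactly one of depth or voxel_size")
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (!is.null(depth)) {
    depth <- as.integer(depth)
    if (depth < 0L) stop("depth must be >= 0")
    side <- max(hi - lo)
    if (side <= 0) side <- 1e-9
    voxel_size <- side / 2^depth
  } else {
    if (voxel_size <= 0) stop("voxel_size must be positive")
    depth <- as.integer(ceiling(log2(max(max(hi - lo), voxel_size) / voxel_size)))
  }
  nn <- stats::median(apply(pts, 2, function(v) stats::median(abs(diff(sort(unique(v))))) ), na.rm = TRUE)
  if (is.finite(nn) && nn > 0 && voxel_size < nn / 2)
    warning("voxel_size is small relative to point spacing; surface holes likely")
  if (is.null(origin)) {
    origin <- lo - voxel_size
  } else {
    origin <- as.numeric(origin)
    if (any(pts[, 1] < origin[1]) || any(pts[, 2] < origin[2]) || any(pts[, 3] < origin[3]))
      stop("origin must not exceed the cloud minimum")
  }
  idx <- floor(sweep(sweep(pts, 2, origin), 2, voxel_size, "/")) + 1L
  storage.mode(idx) <- "integer"
  dims <- apply(idx, 2, max) + 1L           # +1 void padding layer at the top
  occ <- array(FALSE, dims)
  occ[lin_index(idx, dims)] <- TRUE
  voxel_grid(occ, voxel_size, origin, depth = depth)
}

#' Neighbors of a cell under 6/18/26-connectivity
#'
#' Face-, face+edge-, or face+edge+corner-adjacent cells, clipped to the
#' grid bounds.
#'
#' @param grid a `voxel_grid` (only its dims are used).
#' @param index length-3 integer cell index.
#' @param code connectivity, one of 6, 18, 26.
#' @return integer matrix of neighbor indices.
#' @export
neighbors <- function(grid, index, code = 26L) {
  d <- dim(grid$occ)
  index <- as.integer(index)
  if (length(index) != 3L || any(index < 1L) || any(index > d))
    stop("index out of grid bounds")
  off <- neighbor_offsets(code)
  nb <- sweep(off, 2, index, "+")
  keep <- nb[, 1] >= 1L & nb[, 2] >= 1L & nb[, 3] >= 1L &
    nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
  nb[keep, , drop = FALSE]
}

# adjacency edge list among cells of `idx` under a connectivity code,
# as a 2-column matrix of row numbers into idx
adjacency_pairs <- function(idx, dims, code = 26L) {
  if (nrow(idx) == 0L) return(matrix(integer(0), ncol = 2))
  lin <- lin_index(idx, dims)
  pos <- integer(prod(dims))
  pos[lin] <- seq_len(nrow(idx))
  off <- neighbor_offsets(code)
  off <- off[seq_len(nrow(off)) <= nrow(off) / 2, , drop = FALSE]  # half: undirected
  out <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    nb <- sweep(idx, 2, o, "+")
    ok <- nb[, 1] >= 1L & nb[, 2] >= 1L & nb[, 3] >= 1L &
      nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nl <- lin_index(nb[ok, , drop = FALSE], dims)
    p <- pos[nl]
    hit <- p > 0L
    if (!any(hit)) next
    out[[r]] <- cbind(which(ok)[hit], p[hit])
  }
  do.call(rbind, c(out, list(matrix(integer(0), ncol = 2))))
}

#' Connected components of a cell set
#'
#' Partitions a set of lattice cells into maximal n-connected groups,
#' returned sorted by size (largest first).  Ties keep the group whose
#' smallest member comes first in column-major order, so the partition is
#' independent of the input enumeration order.
#'
#' @param grid a `voxel_grid` (bounds only).
#' @param cell_set n x 3 index matrix; defaults to the occupied cells.
#' @param code connectivity code (6, 18 or 26).
#' @return list of index matrices.
#' @export
connected_components <- function(grid, cell_set = occupied_indices(grid), code = 26L) {
  idx <- idx_matrix(cell_set)
  if (nrow(idx) == 0L) return(list())
  dims <- dim(grid$occ)
  ed <- adjacency_pairs(idx, dims, code)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(nrow(idx)), memb)
  comps <- lapply(comps, function(r) idx[r, , drop = FALSE])
  sizes <- vapply(comps, nrow, integer(1))
  firsts <- vapply(comps, function(m) min(lin_index(m, dims)), numeric(1))
  unname(comps[order(-sizes, firsts)])
}

# ---- plain-text serialization ----------------------------------------------

#' Write / read a voxel grid as columnar text plus a JSON header
#'
#' `<path>` receives one `i j k` triple per line; `<path>.json` holds dims,
#' origin, voxel_size and depth.
#'
#' @param grid a `voxel_grid`.
#' @param path output path for the index table.
#' @export
write_grid <- function(grid, path) {
  idx <- occupied_indices(grid)
  utils::write.table(idx, path, row.names = FALSE, col.names = FALSE)
  hdr <- list(dims = dim(grid$occ), origin = grid$origin,
              voxel_size = grid$voxel_size, depth = grid$depth)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  idx <- as.matrix(utils::read.table(path))
  voxel_grid(idx, hdr$voxel_size, hdr$origin, dims = hdr$dims,
             depth = if (is.null(hdr$depth)) NA_integer_ else hdr$depth)
}
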