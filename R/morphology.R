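# Voxel denoising, surface-hole filling and internal space filling.

#' Delete noise voxels not 6-connected to the main object body
#'
#' Keeps only the largest 6-connected component of object voxels.  A
#' 26-connected check would leave too many loose ends that end up in the
#' skeleton, so the stricter face-connectivity is used.
#'
#' @param grid a `voxel_grid` with at least one object voxel.
#' @param keep_first on a tie for largest component, keep the one whose
#'   first cell comes earliest in column-major order instead of failing.
#'   Ties are pathological on real data, so the default is to fail loudly.
#' @return the denoised `voxel_grid`; the number of removed voxels is
#'   attached as attribute `"removed"`.
#' @export
denoise <- function(grid, keep_first = FALSE) {
  if (sum(grid$occ) == 0L) stop("empty grid")
  comps <- connected_components(grid, code = 6L)
  if (length(comps) > 1L && nrow(comps[[1]]) == nrow(comps[[2]]) && !keep_first)
    stop("tie for largest 6-connected component; pass keep_first = TRUE ",
         "to keep the first in index order")
  main <- comps[[1]]
  occ <- array(FALSE, dim(grid$occ))
  occ[lin_index(main, dim(grid$occ))] <- TRUE
  out <- grid_replace_occ(grid, occ)
  attr(out, "removed") <- sum(grid$occ) - nrow(main)
  out
}

#' A manual fill list
#'
#' Records the voxels filled by hand in the surface-filling step (occlusion
#' holes, caps over branch ends that leave the model space), so the manual
#' step is reproducible and versionable.
#'
#' @param indices n x 3 matrix of lattice triples to force to object.
#' @param label free-text description (e.g. "occlusion under deck").
#' @param voxel_size_check optional voxel size the list was authored for;
#'   checked against the grid on application.
#' @return a `fill_list`.
#' @export
fill_list <- function(indices, label = "", voxel_size_check = NULL) {
  structure(list(indices = idx_matrix(indices), label = label,
                 voxel_size_check = voxel_size_check),
            class = "fill_list")
}

#' Read / write a fill list as JSON
#'
#' Format: `{"voxel_size_check": float, "fills": [[i,j,k], ...],
#' "label": str}`.
#'
#' @param path JSON file path.
#' @export
read_fill_list <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- x$fills
  if (is.list(fl)) fl <- do.call(rbind, fl)
  fill_list(fl, label = if (is.null(x$label)) "" else x$label,
            voxel_size_check = x$voxel_size_check)
}

#' @rdname read_fill_list
#' @param fills a `fill_list`.
#' @export
write_fill_list <- function(fills, path) {
  jsonlite::write_json(
    list(voxel_size_check = fills$voxel_size_check,
         fills = unname(as.matrix(fills$indices)), label = fills$label),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fill surface holes and open branch ends
#'
#' Sets the listed cells to object.  Idempotent; filling an already-object
#' cell raises a warning, not an error.
#'
#' @param grid a `voxel_grid`.
#' @param fills a `fill_list` (or bare n x 3 index matrix).
#' @return the filled `voxel_grid`.
#' @export
fill_surface <- function(grid, fills) {
  idx <- if (inherits(fills, "fill_list")) fills$indices else idx_matrix(fills)
  if (inherits(fills, "fill_list") && !is.null(fills$voxel_size_check) &&
      abs(fills$voxel_size_check - grid$voxel_size) >
        1e-9 * grid$voxel_size)
    warning("fill list was authored for voxel size ", fills$voxel_size_check,
            " but the grid has ", grid$voxel_size)
  if (nrow(idx) == 0L) return(grid)
  d <- dim(grid$occ)
  if (any(idx < 1L) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3]))
    stop("fill index outside grid dims")
  lin <- lin_index(idx, d)
  already <- grid$occ[lin]
  if (any(already))
    warning(sum(already), " fill cell(s) already object")
  occ <- grid$occ
  occ[lin] <- TRUE
  grid_replace_occ(grid, occ)
}

#' Suggest candidate surface holes
#'
#' Advisory helper for the manual filling step: void cells with at least
#' `min_object_face_neighbors` object 6-neighbours, ranked by that count.
#' Never applied automatically.
#'
#' @param grid a `voxel_grid`.
#' @param min_object_face_neighbors threshold (default 4: a one-cell
#'   puncture in a flat surface has 4).
#' @return index matrix ordered by decreasing neighbour count, with the
#'   counts attached as attribute `"count"`.
#' @export
suggest_holes <- function(grid, min_object_face_neighbors = 4L) {
  A <- grid$occ
  cnt <- array(0L, dim(A))
  for (f in seq_len(6L)) cnt <- cnt + shift3(A, face_dirs[f, ])
  hit <- !A & cnt >= min_object_face_neighbors
  idx <- which(hit, arr.ind = TRUE)
  dimnames(idx) <- NULL
  ord <- order(-cnt[hit])
  out <- idx[ord, , drop = FALSE]
  attr(out, "count") <- cnt[hit][ord]
  out
}

#' Fill internal spaces
#'
#' Void voxels are assumed to be either external -- a single group
#' 6-connected to the grid boundary -- or internal.  A flood fill from the
#' boundary marks the external void; every unreached void cell becomes
#' object, so the result has no cavities.
#'
#' @param grid a `voxel_grid`, padded so boundary cells are void (as
#'   produced by [voxelize()]).
#' @return the filled `voxel_grid`; number of filled cells attached as
#'   attribute `"filled"`.
#' @export
fill_internal <- function(grid) {
  grid <- pad_if_needed(grid)
  A <- grid$occ
  d <- dim(A)
  void <- !A
  reach <- array(FALSE, d)
  # seed: all boundary void cells
  reach[1, , ] <- void[1, , ]; reach[d[1], , ] <- void[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | void[, 1, ]; reach[, d[2], ] <- reach[, d[2], ] | void[, d[2], ]
  reach[, , 1] <- reach[, , 1] | void[, , 1]; reach[, , d[3]] <- reach[, , d[3]] | void[, , d[3]]
  repeat {
    grown <- reach
    for (f in seq_len(6L)) grown <- grown | shift3(reach, face_dirs[f, ])
    grown <- grown & void
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  internal <- void & !reach
  occ <- A | internal
  out <- grid_replace_occ(grid, occ)
  attr(out, "filled") <- sum(internal)
  out
}
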