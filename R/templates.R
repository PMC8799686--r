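# Deletion templates for directional sequential thinning.
#
# Each template inspects the 26 neighbours in the 3x3x3 block around a
# candidate voxel and assigns a subset of positions to "object" and a
# subset to "void"; unmarked positions are free.  Cells outside the grid
# count as void.  The four base families describe the four local surface
# situations a border voxel of a tubular solid can present, and their
# rotation-orbit sizes under the 24 proper cube rotations are fixed by
# their symmetry groups:
#
#   A  face border (normal +z): the cell above is void and the cell below
#      is object -- the workhorse directional border detector.  Symmetric
#      under the 4 rotations about z -> 6 unique configurations.
#   B  convex edge / diagonal ridge (between +y and +z): the two outward
#      faces and the edge cell between them are void, the opposite
#      edge-diagonal is object.  One 2-fold symmetry -> 12 configurations.
#   C  convex corner (+x+y+z): the whole outward octant (7 cells) is void,
#      the opposite corner diagonal is object -- cleans 3D corners and
#      diagonal strand tips.  3-fold symmetry about the corner diagonal
#      -> 8 configurations.
#   D  rim of a plate or side of a strand (strand axis z, rim toward +x):
#      the rim face, both in-plane lateral faces and their edge cells are
#      void, the two cells along the strand axis are object -- erodes
#      one-voxel-thick ribbons towards their midline and removes columns
#      that hang diagonally off a chain.  One 2-fold symmetry -> 12.
#
# Every template marks at least one void face neighbour, so interior
# voxels never match, and at least one object cell, so isolated voxels
# never match.  The masks leave the remaining positions free: whether a
# nominated border voxel may actually be removed is decided by the four
# P-simplicity deletion criteria, while the masks control the direction
# and order in which the surface is eaten.  Curve-end voxels (at most one
# 26-adjacent object voxel) are excluded from candidacy by [thin()] so
# terminal branches survive.

template_mask <- function(family, object, void, rotation_id = 0L) {
  object <- idx_matrix(object); void <- idx_matrix(void)
  if (nrow(object) < 1L) stop("template must mark >= 1 object cell")
  if (!any(rowSums(abs(void)) == 1L))
    stop("template must mark at least one void face neighbour")
  both <- rbind(object, void)
  if (anyDuplicated(rbind(both)) > 0L)
    stop("object/void assignments overlap")
  if (any(apply(abs(both), 1, max) > 1L) || any(rowSums(abs(both)) == 0L))
    stop("template offsets must lie in the 26-neighbourhood")
  structure(list(family = family, rotation_id = as.integer(rotation_id),
                 object = object, void = void),
            class = "template_mask")
}

#' @export
print.template_mask <- function(x, ...) {
  cat(sprintf("<template_mask %s/%d> %d object, %d void cells\n",
              x$family, x$rotation_id, nrow(x$object), nrow(x$void)))
  invisible(x)
}

#' The four base deletion templates
#'
#' Returns the base masks of families A (flat surface), B (edge/ridge),
#' C (corner) and D (plate rim); see the package vignette for the
#' transcription rationale.  Under all 24 proper cube rotations they expand
#' to 6, 12, 8 and 12 unique configurations (38 in total).
#'
#' @return list of 4 `template_mask` objects.
#' @export
base_templates <- function() {
  list(
    A = template_mask("A",
      object = rbind(c(0, 0, -1)),
      void   = rbind(c(0, 0, 1))),
    B = template_mask("B",
      object = rbind(c(0, -1, -1)),
      void   = rbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 1))),
    C = template_mask("C",
      object = rbind(c(-1, -1, -1)),
      void   = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                     c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))),
    D = template_mask("D",
      object = rbind(c(0, 0, 1), c(0, 0, -1)),
      void   = rbind(c(1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(1, 1, 0), c(1, -1, 0)))
  )
}

# the 24 proper rotation matrices of the cube
cube_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- list()
  for (p in perms) {
    P <- diag(3)[p, ]
    for (s in seq_len(nrow(signs))) {
      R <- diag(as.numeric(signs[s, ])) %*% P
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
    }
  }
  stopifnot(length(out) == 24L)
  out
}

rotate_offsets <- function(off, R) {
  m <- t(R %*% t(off))
  storage.mode(m) <- "integer"
  m
}

canon_sig <- function(object, void) {
  key <- function(m) paste(m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE],
                           collapse = ",")
  paste(key(object), "|", key(void))
}

#' Expand base templates under all proper cube rotations
#'
#' Applies the 24 proper rotations to each base mask and removes duplicate
#' patterns, yielding the directional configurations used by [thin()]:
#' 6 for family A, 12 for B, 8 for C and 12 for D -- 38 in all, ordered
#' A-rotations first, then B, C, D.
#'
#' @param templates output of [base_templates()].
#' @return list of `template_mask` objects with rotation ids.
#' @export
expand_rotations <- function(templates = base_templates()) {
  rots <- cube_rotations()
  out <- list()
  seen_all <- character()
  for (tm in templates) {
    seen <- character()
    rid <- 0L
    for (R in rots) {
      ob <- rotate_offsets(tm$object, R)
      vd <- rotate_offsets(tm$void, R)
      sig <- canon_sig(ob, vd)
      if (sig %in% seen) next
      if (sig %in% seen_all)
        stop("internal consistency error: duplicate template across families")
      seen <- c(seen, sig)
      seen_all <- c(seen_all, sig)
      rid <- rid + 1L
      out[[length(out) + 1L]] <- template_mask(tm$family, ob, vd,
                                               rotation_id = rid)
    }
  }
  out
}

#' Does a voxel's neighbourhood match a template?
#'
#' True iff every object-marked position holds an object voxel and every
#' void-marked position a void voxel (cells outside the grid count as
#' void).  Free positions are unconstrained.
#'
#' @param grid a `voxel_grid`.
#' @param index length-3 index of an object voxel.
#' @param mask a `template_mask`.
#' @return logical.
#' @export
matches <- function(grid, index, mask) {
  d <- dim(grid$occ)
  index <- as.integer(index)
  if (!grid$occ[index[1], index[2], index[3]])
    stop("matches() requires an object voxel")
  at <- function(p) {
    if (any(p < 1L) || any(p > d)) return(FALSE)
    grid$occ[p[1], p[2], p[3]]
  }
  for (r in seq_len(nrow(mask$object)))
    if (!at(index + mask$object[r, ])) return(FALSE)
  for (r in seq_len(nrow(mask$void)))
    if (at(index + mask$void[r, ])) return(FALSE)
  TRUE
}

# vectorized: logical array of cells matching the mask (object cells only)
match_array <- function(A, mask) {
  ok <- A
  for (r in seq_len(nrow(mask$object)))
    ok <- ok & shift3(A, mask$object[r, ])
  for (r in seq_len(nrow(mask$void)))
    ok <- ok & !shift3(A, mask$void[r, ])
  ok
}
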