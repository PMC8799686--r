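# Sequential, directional, template-driven thinning with adjusted
# P-simplicity deletion criteria and per-voxel iteration-of-exposure
# bookkeeping.

# face direction order: +x, -x, +y, -y, +z, -z
face_dirs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
face_names <- c("xplus", "xminus", "yplus", "yminus", "zplus", "zminus")

# number of connected components of `sel` (block position ids) under the
# given adjacency list
block_components <- function(sel, adj) {
  if (length(sel) == 0L) return(0L)
  inset <- logical(27L); inset[sel] <- TRUE
  seen <- logical(27L)
  ncomp <- 0L
  for (s in sel) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s; seen[s] <- TRUE
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb) > 0L) { seen[nb] <- TRUE; stack <- c(stack, nb) }
    }
  }
  ncomp
}

# the four deletion criteria for one candidate.
# block: logical 27-vector of the object state around x (sub-pass start);
# cand_block: logical 27-vector of candidate membership around x.
criteria_ok <- function(block, cand_block) {
  obj <- which(block[.vx$pos26]) ; obj <- .vx$pos26[obj]
  # (a) all 26-adjacent object voxels form a single 26-connected component
  if (block_components(obj, .vx$adj26) != 1L) return(FALSE)
  # (b) all 18-adjacent void voxels form a single 6-connected component
  v18 <- .vx$pos18[!block[.vx$pos18]]
  if (block_components(v18, .vx$adj6_18) != 1L) return(FALSE)
  # (c) every 26-adjacent candidate y needs an object z 26-adjacent to both
  ys <- .vx$pos26[cand_block[.vx$pos26]]
  for (y in ys) {
    z <- .vx$adj26[[y]]
    if (!any(block[z] & z != y)) return(FALSE)
  }
  # (d) every 6-adjacent candidate y needs void voxels z, t forming a unit
  #     square with x and y
  y6 <- .vx$pos6[cand_block[.vx$pos6]]
  for (y in y6) {
    found <- FALSE
    for (pq in .vx$unit_squares[[y]]) {
      if (!block[pq[1]] && !block[pq[2]]) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Adjusted P-simplicity deletion test
#'
#' Checks the four deletion criteria for an object voxel `x` against the
#' current grid and the candidate set of the running sub-pass: (a) the
#' 26-adjacent object voxels form a single 26-connected component; (b) the
#' 18-adjacent void voxels form a single 6-connected component (6-adjacency
#' within the 3x3x3 block); (c) for every 26-adjacent candidate `y` there is
#' an object voxel `z` 26-adjacent to both `x` and `y` (any object voxel,
#' not only non-deletable ones -- the adjustment that yields one-voxel-thick
#' skeletons); (d) for every 6-adjacent candidate `y` there are two void
#' voxels completing a unit square with `x` and `y`.  Criteria (c) and (d)
#' are vacuously satisfied when no such `y` exists.
#'
#' @param grid a `voxel_grid`.
#' @param x length-3 index of the candidate voxel.
#' @param candidate_set n x 3 index matrix of all template-matching voxels
#'   of the current sub-pass (must contain `x`).
#' @return logical.
#' @export
is_deletable <- function(grid, x, candidate_set) {
  x <- as.integer(x)
  d <- dim(grid$occ)
  cand <- idx_matrix(candidate_set)
  lin_x <- lin_index(matrix(x, 1), d)
  if (!any(lin_index(cand, d) == lin_x))
    stop("contract violation: x is not in candidate_set")
  A <- grid$occ
  C <- array(FALSE, d)
  C[lin_index(cand, d)] <- TRUE
  blk <- function(arr) {
    out <- logical(27L)
    for (p in seq_len(27L)) {
      q <- x + .vx$off27[p, ]
      out[p] <- !(any(q < 1L) || any(q > d)) && arr[q[1], q[2], q[3]]
    }
    out
  }
  criteria_ok(blk(A), blk(C))
}

pad_if_needed <- function(grid) {
  A <- grid$occ
  d <- dim(A)
  touches <- any(A[1, , ]) || any(A[d[1], , ]) || any(A[, 1, ]) ||
    any(A[, d[2], ]) || any(A[, , 1]) || any(A[, , d[3]])
  if (!touches) return(grid)
  B <- array(FALSE, d + 2L)
  B[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- A
  voxel_grid(B, grid$voxel_size, grid$origin - grid$voxel_size,
             depth = grid$depth)
}

#' Thin a voxel solid to a curve skeleton
#'
#' Sequential directional thinning.  Each full cycle runs the 38 template
#' configurations as sub-passes in the fixed order A-rotations, then B, C,
#' D.  Per sub-pass all object voxels matching the configuration form the
#' candidate set, each candidate is tested with the four deletion criteria
#' against the grid state at sub-pass start, and all passing voxels are
#' deleted simultaneously.  The loop terminates when a full cycle deletes
#' nothing.  Whenever an object voxel's face neighbour becomes void the
#' full-cycle index is logged as that face's iteration of exposure
#' (initially exposed faces count as iteration 0); the ordered values
#' `I1 <= I2 <= I3 <= I4` of each surviving voxel summarise how long each
#' of its first four faces stayed buried, a proxy for the local radius.
#'
#' @param grid a denoised, internally filled `voxel_grid`.
#' @param record_exposure keep per-face exposure iterations (needed for
#'   volume reconstruction).
#' @param audit record every deletion (cell, cycle, sub-pass, order) so the
#'   run can be replayed against an independent simple-point oracle.
#' @return an object of class `skeleton`: the surviving grid plus a
#'   `voxels` data frame with indices, world coordinates, `I1..I4` and the
#'   exposed-face count, the per-direction exposure matrix, the number of
#'   thinning cycles, and (optionally) the audit log.
#' @export
thin <- function(grid, record_exposure = TRUE, audit = FALSE) {
  grid <- pad_if_needed(grid)
  A <- grid$occ
  d <- dim(A)
  if (sum(A) == 0L) stop("empty grid: nothing to thin")
  tpls <- .vx$templates38
  if (is.null(tpls)) {
    tpls <- expand_rotations(base_templates())
    .vx$templates38 <- tpls
  }
  nface <- 6L
  E <- array(NA_integer_, c(d, nface))
  for (f in seq_len(nface))
    E[, , , f][A & !shift3(A, face_dirs[f, ])] <- 0L
  audit_log <- if (audit) list() else NULL
  nb26 <- array(0L, d)
  for (q in seq_len(26L)) nb26 <- nb26 + shift3(A, .vx$N26[q, ])
  max_cycles <- max(d) + 1L
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    if (cycle > max_cycles)
      stop("internal error: thinning failed to terminate after ",
           max_cycles, " cycles")
    deleted_cycle <- 0L
    # the candidate pool of a cycle is frozen to the voxels already
    # face-exposed at cycle start: deeper voxels are returned to the set
    # for the next thinning iteration, so each cycle erodes at most one
    # shell and the exposure iteration counts local radius in voxels
    border <- array(FALSE, d)
    for (f in seq_len(6L)) border <- border | !shift3(A, face_dirs[f, ])
    border <- border & A
    for (s in seq_along(tpls)) {
      # voxels with <= 1 object 26-neighbour are curve ends (or isolated)
      # and are never candidates -- terminal branches survive
      M <- match_array(A, tpls[[s]]) & border & (nb26 >= 2L)
      cand <- which(M, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
        blk  <- as.vector(A[(i - 1L):(i + 1L), (j - 1L):(j + 1L),
                            (k - 1L):(k + 1L)])
        cblk <- as.vector(M[(i - 1L):(i + 1L), (j - 1L):(j + 1L),
                            (k - 1L):(k + 1L)])
        keep[r] <- criteria_ok(blk, cblk)
      }
      if (!any(keep)) next
      del <- cand[keep, , drop = FALSE]
      A[lin_index(del, d)] <- FALSE
      deleted_cycle <- deleted_cycle + nrow(del)
      # keep the 26-neighbour counts current
      for (q in seq_len(26L)) {
        nb <- sweep(del, 2, .vx$N26[q, ], "+")
        ok <- nb[, 1] >= 1L & nb[, 2] >= 1L & nb[, 3] >= 1L &
          nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
        if (any(ok)) {
          ln <- lin_index(nb[ok, , drop = FALSE], d)
          nb26[ln] <- nb26[ln] - 1L
        }
      }
      # newly exposed faces: the neighbour opposite each face direction
      for (f in seq_len(nface)) {
        nb <- sweep(del, 2, face_dirs[f, ], "-")
        ok <- nb[, 1] >= 1L & nb[, 2] >= 1L & nb[, 3] >= 1L &
          nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        linf <- lin_index(nb, d) + prod(d) * (f - 1L)
        upd <- A[lin_index(nb, d)] & is.na(E[linf])
        E[linf[upd]] <- cycle
      }
      if (audit)
        audit_log[[length(audit_log) + 1L]] <-
          cbind(del, cycle = cycle, subpass = s, ord = seq_len(nrow(del)))
    }
    if (deleted_cycle == 0L) break
  }
  surv <- which(A, arr.ind = TRUE)
  dimnames(surv) <- NULL
  lins <- lin_index(surv, d)
  Emat <- matrix(NA_integer_, nrow(surv), nface,
                 dimnames = list(NULL, face_names))
  for (f in seq_len(nface)) Emat[, f] <- E[lins + prod(d) * (f - 1L)]
  sortedI <- t(apply(Emat, 1L, function(v) {
    v <- sort(v[!is.na(v)])
    c(v, rep(NA_integer_, 4L))[1:4]
  }))
  colnames(sortedI) <- c("I1", "I2", "I3", "I4")
  ctr <- voxel_centers(grid, surv)
  vox <- data.frame(i = surv[, 1], j = surv[, 2], k = surv[, 3],
                    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                    I1 = sortedI[, 1], I2 = sortedI[, 2],
                    I3 = sortedI[, 3], I4 = sortedI[, 4],
                    exposed_faces = rowSums(!is.na(Emat)))
  structure(
    list(grid = grid_replace_occ(grid, A), voxels = vox,
         exposure_dirs = Emat, cycles = cycle - 1L,
         audit = if (audit) {
           al <- do.call(rbind, audit_log)
           colnames(al) <- c("i", "j", "k", "cycle", "subpass", "ord")
           as.data.frame(al)
         } else NULL),
    class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels after %d thinning cycles, voxel %.4g m\n",
              nrow(x$voxels), x$cycles, x$grid$voxel_size))
  invisible(x)
}

#' @export
summary.skeleton <- function(object, ...) {
  v <- object$voxels
  cat(sprintf("skeleton of %d voxels (%d thinning cycles)\n",
              nrow(v), object$cycles))
  cat(sprintf("exposed faces: min %d, median %g\n",
              min(v$exposed_faces), stats::median(v$exposed_faces)))
  cat("iterations of exposure (I1..I4):\n")
  print(summary(v[, c("I1", "I2", "I3", "I4")]))
  invisible(object)
}

skeleton_occupancy <- function(x) {
  if (inherits(x, "skeleton")) x$grid else x
}

# classical local simple-point characterisation: the object neighbours
# form one 26-component and the void 6-neighbours belong to one
# 6-component of void within the 18-neighbourhood
is_simple_local <- function(block) {
  obj <- .vx$pos26[block[.vx$pos26]]
  if (length(obj) == 0L) return(FALSE)
  if (block_components(obj, .vx$adj26) != 1L) return(FALSE)
  v18 <- .vx$pos18[!block[.vx$pos18]]
  if (!any(.vx$pos6 %in% v18)) return(FALSE)
  if (block_components(v18, .vx$adj6_18) != 1L) return(FALSE)
  # the single void component must touch a face neighbour (it does, since
  # all face voids are in v18 and v18 is one component containing them)
  TRUE
}

#' Is a skeleton one voxel thick?
#'
#' True iff no non-curve-end voxel can be removed without changing the
#' local topology (a simple-point test per voxel): the operational
#' definition of thinness.  Curve ends (voxels with at most one 26-adjacent
#' object voxel) are exempt, since deleting them erodes branches rather
#' than thickness.
#'
#' @param x a `skeleton` or a `voxel_grid` holding a thinning output.
#' @return logical; offending voxel indices are attached as attribute
#'   `"removable"` when FALSE.
#' @export
thinness_check <- function(x) {
  grid <- pad_if_needed(skeleton_occupancy(x))
  A <- grid$occ
  idx <- which(A, arr.ind = TRUE)
  bad <- matrix(integer(0), 0, 3)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    blk <- as.vector(A[(i - 1L):(i + 1L), (j - 1L):(j + 1L), (k - 1L):(k + 1L)])
    nnb <- sum(blk[.vx$pos26])
    if (nnb <= 1L) next                      # curve end / isolated
    if (is_simple_local(blk)) bad <- rbind(bad, idx[r, ])
  }
  out <- nrow(bad) == 0L
  attr(out, "removable") <- bad
  out
}
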