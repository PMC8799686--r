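# Independent brute-force oracles used to cross-check the package's
# topology and geometry code.  Deliberately naive: plain BFS over index
# matrices and string-keyed cell counting, sharing no code path with the
# package implementation (which uses igraph labelling and numeric-encoded
# cubical complexes).

# connected components of an n x 3 index set by breadth-first search
oracle_components <- function(idx, code = 26L) {
  idx <- as.matrix(idx)
  n <- nrow(idx)
  if (n == 0L) return(list())
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  row_of <- new.env(parent = emptyenv())
  for (r in seq_len(n)) assign(key[r], r, envir = row_of)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (code == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (code == 18L) offs <- offs[apply(abs(offs), 1, max) == 1 &
                                  rowSums(abs(offs)) <= 2, , drop = FALSE]
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        nb <- idx[v, ] + offs[r, ]
        w <- mget(paste(nb[1], nb[2], nb[3]), envir = row_of,
                  ifnotfound = list(NULL))[[1]]
        if (!is.null(w) && !seen[w]) {
          seen[w] <- TRUE; queue <- c(queue, w); members <- c(members, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- idx[members, , drop = FALSE]
  }
  comps
}

# Euler characteristic of the cubical complex by exhaustive cell counting
oracle_euler <- function(idx) {
  idx <- as.matrix(idx)
  verts <- character(0); edges <- character(0); faces <- character(0)
  vs <- new.env(parent = emptyenv())
  es <- new.env(parent = emptyenv())
  fs <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(idx))) {
    c0 <- idx[r, ]
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      assign(paste(c0[1] + a, c0[2] + b, c0[3] + cc), TRUE, envir = vs)
    for (ax in 1:3) {
      o1 <- setdiff(1:3, ax)
      for (a in 0:1) for (b in 0:1) {
        p <- c0; p[o1[1]] <- p[o1[1]] + a; p[o1[2]] <- p[o1[2]] + b
        assign(paste(ax, p[1], p[2], p[3]), TRUE, envir = es)
      }
      for (a in 0:1) {
        p <- c0; p[ax] <- p[ax] + a
        assign(paste(ax, p[1], p[2], p[3]), TRUE, envir = fs)
      }
    }
  }
  length(ls(vs)) - length(ls(es)) + length(ls(fs)) - nrow(idx)
}

# Betti triple (components, loops, cavities) of an occupancy array:
# 26-connectivity for the object, 6-connectivity for the void, loops
# derived from the Euler characteristic
oracle_betti <- function(A) {
  d <- dim(A)
  obj <- which(A, arr.ind = TRUE)
  if (nrow(obj) == 0L) return(c(0L, 0L, 0L))
  b0 <- length(oracle_components(obj, 26L))
  void <- which(!A, arr.ind = TRUE)
  vcomps <- oracle_components(void, 6L)
  b2 <- sum(vapply(vcomps, function(m)
    !(any(m == 1L) || any(m[, 1] == d[1]) || any(m[, 2] == d[2]) ||
        any(m[, 3] == d[3])), logical(1)))
  chi <- oracle_euler(obj)
  c(b0, b0 + b2 - chi, b2)
}

oracle_betti_grid <- function(grid) oracle_betti(grid$occ)

# brute-force union-find over a cell set (for cross-checking the
# component partition)
oracle_union_find <- function(idx, code = 26L) {
  idx <- as.matrix(idx)
  n <- nrow(idx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lim <- if (code == 6L) 1L else 3L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    dd <- abs(idx[i, ] - idx[j, ])
    adj <- if (code == 6L) sum(dd) == 1L else
      (max(dd) <= 1L && sum(dd) > 0L &&
         (code == 26L || sum(dd) <= 2L))
    if (adj) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# small convenience: bar/box grid builders
solid_box_grid <- function(dims_inner, voxel_size = 0.01) {
  d <- dims_inner + 2L
  A <- array(FALSE, d)
  A[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)] <- TRUE
  voxel_grid(A, voxel_size)
}

chain_grid <- function(n, voxel_size = 0.01) {
  A <- array(FALSE, c(3, 3, n + 2L))
  A[2, 2, 2:(n + 1L)] <- TRUE
  voxel_grid(A, voxel_size)
}

# disjoint union of two phantoms' occupancy in one grid (second shifted in x)
two_phantom_grid <- function(ph1, ph2, gap = 3L) {
  o1 <- ph1$occupancy
  shift <- max(o1[, 1]) + gap
  o2 <- ph2$occupancy
  o2[, 1] <- o2[, 1] + shift
  occ <- rbind(o1, o2) + 1L
  dims <- apply(occ, 2, max) + 1L
  voxel_grid(occ, ph1$voxel_size, dims = dims)
}
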