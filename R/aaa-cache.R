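# Shared internal helpers and precomputed neighbourhood structures.
# This file collates first; everything here is load-time infrastructure.

# Shift a logical 3D array by an integer offset: out[i,j,k] = A[i+o1, j+o2, k+o3],
# cells falling outside the array are FALSE (outside the grid counts as void).
shift3 <- function(A, o) {
  d <- dim(A)
  out <- array(FALSE, d)
  i1 <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
  i2 <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
  i3 <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
  if (length(i1) < 1L || length(i2) < 1L || length(i3) < 1L) return(out)
  out[i1, i2, i3] <- A[i1 + o[1], i2 + o[2], i3 + o[3]]
  out
}

idx_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != 3L) stop("index matrix must have 3 columns")
  dimnames(x) <- NULL
  x
}

# linear (column-major) index of an n x 3 index matrix
lin_index <- function(idx, dims) {
  idx[, 1L] + dims[1L] * (idx[, 2L] - 1L) + dims[1L] * dims[2L] * (idx[, 3L] - 1L)
}

neighbor_offsets <- function(code = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dimnames(g) <- NULL
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  n1 <- rowSums(abs(g))
  cheb <- apply(abs(g), 1L, max)
  keep <- switch(as.character(code),
    "6"  = n1 == 1L,
    "18" = cheb == 1L & n1 <= 2L,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity code must be one of 6, 18, 26")
  )
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

.vx <- new.env(parent = emptyenv())
.vx$N6  <- neighbor_offsets(6L)
.vx$N18 <- neighbor_offsets(18L)
.vx$N26 <- neighbor_offsets(26L)

# 27-cell block bookkeeping (column-major order of a [-1,1]^3 array:
# dx fastest, then dy, then dz; center is position 14)
.vx$off27 <- {
  m <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
.vx$center27 <- 14L
.vx$pos26 <- setdiff(seq_len(27L), .vx$center27)
.vx$chb <- apply(abs(.vx$off27), 1L, max)
.vx$l1  <- rowSums(abs(.vx$off27))
.vx$pos18 <- which(.vx$chb == 1L & .vx$l1 <= 2L)
.vx$pos6  <- which(.vx$l1 == 1L)

# adjacency lists among block positions
.vx$adj26 <- lapply(seq_len(27L), function(p) {
  if (p == .vx$center27) return(integer(0))
  q <- setdiff(.vx$pos26, p)
  d <- abs(sweep(.vx$off27[q, , drop = FALSE], 2, .vx$off27[p, ]))
  q[apply(d, 1, max) <= 1L]
})
.vx$adj6_18 <- lapply(seq_len(27L), function(p) {
  if (!(p %in% .vx$pos18)) return(integer(0))
  q <- setdiff(.vx$pos18, p)
  d <- abs(sweep(.vx$off27[q, , drop = FALSE], 2, .vx$off27[p, ]))
  q[rowSums(d) == 1L]
})
# for criterion (d): for each face position f, the 4 (face p, edge q) void
# pairs forming a unit square with the candidate and its face neighbour f
.vx$unit_squares <- lapply(seq_len(27L), function(f) {
  if (!(f %in% .vx$pos6)) return(NULL)
  of <- .vx$off27[f, ]
  perp <- .vx$pos6[vapply(.vx$pos6, function(p)
    sum(.vx$off27[p, ] * of) == 0L, logical(1))]
  lapply(perp, function(p) {
    oq <- of + .vx$off27[p, ]
    q <- which(.vx$off27[, 1] == oq[1] & .vx$off27[, 2] == oq[2] &
                 .vx$off27[, 3] == oq[3])
    c(p, q)
  })
})
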