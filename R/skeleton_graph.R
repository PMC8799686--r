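# Conversion of the 1-voxel skeleton into a segmented graph of branches,
# joints and curve ends.

#' Classify skeleton voxels by topological role
#'
#' Voxels with one 26-adjacent skeleton voxel are curve ends, with two are
#' regular (branch interior), with three or more joint voxels.  Isolated
#' voxels are labelled curve ends with a warning.
#'
#' @param skeleton a `skeleton` (or `voxel_grid` of skeleton occupancy).
#' @return character vector of roles (`"end"`, `"regular"`, `"joint"`)
#'   aligned with the skeleton voxel order; neighbour counts attached as
#'   attribute `"n_neighbors"`.
#' @export
classify_voxels <- function(skeleton) {
  grid <- skeleton_occupancy(skeleton)
  A <- grid$occ
  idx <- occupied_indices(grid)
  cnt <- array(0L, dim(A))
  for (q in seq_len(26L)) cnt <- cnt + shift3(A, .vx$N26[q, ])
  n <- cnt[lin_index(idx, dim(A))]
  if (any(n == 0L) && nrow(idx) > 1L)
    warning("isolated skeleton voxel(s) labelled as curve ends")
  roles <- ifelse(n <= 1L, "end", ifelse(n == 2L, "regular", "joint"))
  attr(roles, "n_neighbors") <- n
  roles
}

#' Merge joint voxel clusters into true joints
#'
#' Busy junctions exhibit several adjacent joint voxels.  26-connected
#' groups of joint voxels are merged; the member closest to the group
#' centroid becomes the true joint, the others are recorded as associated
#' joint voxels.  Distance ties go to the lowest column-major index (and
#' are logged as a message).
#'
#' @param skeleton a `skeleton`.
#' @param roles output of [classify_voxels()].
#' @return list with `true_joints` (m x 3), `clusters` (list of index
#'   matrices) and `cluster_id` per skeleton voxel (NA outside joints).
#' @export
merge_joint_clusters <- function(skeleton, roles = classify_voxels(skeleton)) {
  grid <- skeleton_occupancy(skeleton)
  idx <- occupied_indices(grid)
  d <- dim(grid$occ)
  jidx <- idx[roles == "joint", , drop = FALSE]
  if (nrow(jidx) == 0L)
    return(list(true_joints = matrix(integer(0), 0, 3), clusters = list(),
                cluster_id = rep(NA_integer_, nrow(idx))))
  comps <- connected_components(grid, jidx, code = 26L)
  true_joints <- matrix(0L, length(comps), 3)
  for (ci in seq_along(comps)) {
    m <- comps[[ci]]
    ctr <- colMeans(m)
    dist2 <- (m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2 + (m[, 3] - ctr[3])^2
    best <- which(dist2 == min(dist2))
    if (length(best) > 1L) {
      best <- best[order(lin_index(m[best, , drop = FALSE], d))][1]
      message("joint centroid tie broken toward lowest index")
    }
    true_joints[ci, ] <- m[best[1], ]
  }
  lin_all <- lin_index(idx, d)
  cid <- rep(NA_integer_, nrow(idx))
  for (ci in seq_along(comps)) {
    cid[match(lin_index(comps[[ci]], d), lin_all)] <- ci
  }
  list(true_joints = true_joints, clusters = comps, cluster_id = cid)
}

#' Segment a skeleton into a graph of branches and joints
#'
#' Walks maximal chains of regular voxels between nodes (curve ends and
#' joint clusters).  Each chain becomes a branch whose polyline geometry is
#' the sequence of voxel centers ("fit between voxel centroids"); pure
#' loops not touching any node are recorded as branches with identical
#' endpoints.
#'
#' @param skeleton a `skeleton`.
#' @param joints output of [merge_joint_clusters()]; computed when omitted.
#' @return an object of class `skeleton_graph` with `nodes` (data frame:
#'   id, kind, i, j, k, x, y, z) and `branches` (list: node ids, ordered
#'   voxel index matrix, voxel count, metric length in metres).
#' @export
segment_branches <- function(skeleton, joints = NULL) {
  grid <- skeleton_occupancy(skeleton)
  roles <- classify_voxels(skeleton)
  if (is.null(joints)) joints <- merge_joint_clusters(skeleton, roles)
  idx <- occupied_indices(grid)
  d <- dim(grid$occ)
  n <- nrow(idx)
  lin_all <- lin_index(idx, d)
  pos <- integer(prod(d)); pos[lin_all] <- seq_len(n)
  # adjacency among skeleton voxels
  adj <- vector("list", n)
  for (q in seq_len(26L)) {
    nb <- sweep(idx, 2, .vx$N26[q, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 2] >= 1L & nb[, 3] >= 1L &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    p <- integer(n); p[ok] <- pos[lin_index(nb[ok, , drop = FALSE], d)]
    hit <- which(p > 0L)
    for (r in hit) adj[[r]] <- c(adj[[r]], p[r])
  }
  cid <- joints$cluster_id
  is_node <- roles != "regular" | !is.na(cid)
  # node table: one node per curve end, one per joint cluster
  node_rows <- which(roles == "end")
  nodes <- data.frame(id = integer(0), kind = character(0),
                      i = integer(0), j = integer(0), k = integer(0))
  nid <- 0L
  node_id_of_voxel <- rep(NA_integer_, n)
  for (r in node_rows) {
    nid <- nid + 1L
    nodes <- rbind(nodes, data.frame(id = nid, kind = "end",
                                     i = idx[r, 1], j = idx[r, 2], k = idx[r, 3]))
    node_id_of_voxel[r] <- nid
  }
  for (ci in seq_along(joints$clusters)) {
    nid <- nid + 1L
    tj <- joints$true_joints[ci, ]
    nodes <- rbind(nodes, data.frame(id = nid, kind = "joint",
                                     i = tj[1], j = tj[2], k = tj[3]))
    node_id_of_voxel[!is.na(cid) & cid == ci] <- nid
  }
  ctr <- voxel_centers(grid, idx)
  branches <- list()
  visited <- logical(n)           # regular voxels consumed by a branch
  walk <- function(start_node_voxel, first_regular) {
    chain <- integer(0)
    prev <- start_node_voxel
    cur <- first_regular
    while (TRUE) {
      chain <- c(chain, cur)
      visited[cur] <<- TRUE
      nxt <- setdiff(adj[[cur]], prev)
      nxt_nodes <- nxt[is_node[nxt]]
      nxt_reg <- nxt[!is_node[nxt] & !visited[nxt]]
      if (length(nxt_nodes) > 0L) return(list(chain = chain, end = nxt_nodes[1]))
      if (length(nxt_reg) == 0L) return(list(chain = chain, end = NA_integer_))
      prev <- cur
      cur <- nxt_reg[1]
    }
  }
  add_branch <- function(v_from, chain, v_to) {
    seqv <- c(v_from, chain, v_to)
    seqv <- seqv[!is.na(seqv)]
    pl <- ctr[seqv, , drop = FALSE]
    len <- if (nrow(pl) > 1L)
      sum(sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
    else 0
    branches[[length(branches) + 1L]] <<- list(
      from = if (is.na(v_from)) NA_integer_ else node_id_of_voxel[v_from],
      to = if (is.na(v_to)) NA_integer_ else node_id_of_voxel[v_to],
      voxels = idx[seqv, , drop = FALSE],
      interior = chain,
      n_voxels = length(seqv),
      length = len)
  }
  # branches emanating from nodes
  for (v in which(is_node)) {
    for (w in adj[[v]]) {
      if (is_node[w]) {
        # direct node-node adjacency: register once (avoid duplicates and
        # intra-cluster pairs)
        if (!is.na(node_id_of_voxel[v]) && !is.na(node_id_of_voxel[w]) &&
            node_id_of_voxel[v] != node_id_of_voxel[w] && v < w)
          add_branch(v, integer(0), w)
      } else if (!visited[w]) {
        res <- walk(v, w)
        add_branch(v, res$chain, res$end)
      }
    }
  }
  # pure loops: cycles of regular voxels touching no node
  for (v in which(!is_node & !visited)) {
    if (visited[v]) next
    res <- walk(v, adj[[v]][1])
    chain <- res$chain              # walk circles back and ends with v
    pl <- ctr[c(chain, chain[1]), , drop = FALSE]
    len <- sum(sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
    branches[[length(branches) + 1L]] <- list(
      from = NA_integer_, to = NA_integer_,
      voxels = idx[chain, , drop = FALSE], interior = chain,
      n_voxels = length(chain), length = len, loop = TRUE)
  }
  wc <- voxel_centers(grid, as.matrix(nodes[, c("i", "j", "k")]))
  nodes$x <- wc[, 1]; nodes$y <- wc[, 2]; nodes$z <- wc[, 3]
  payload <- if (inherits(skeleton, "skeleton")) skeleton$voxels else NULL
  structure(list(nodes = nodes, branches = branches, voxels = idx,
                 roles = roles, cluster_id = cid, payload = payload,
                 voxel_size = grid$voxel_size, origin = grid$origin),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  nk <- table(factor(x$nodes$kind, levels = c("end", "joint")))
  cat(sprintf("<skeleton_graph> %d branches, %d joints, %d curve ends, %d voxels\n",
              length(x$branches), nk[["joint"]], nk[["end"]], nrow(x$voxels)))
  invisible(x)
}

graph_as_igraph <- function(graph) {
  nn <- nrow(graph$nodes)
  loops <- 0L
  el <- matrix(integer(0), 0, 2)
  for (b in graph$branches) {
    f <- b$from; t <- b$to
    if (is.na(f) || is.na(t)) next
    el <- rbind(el, c(f, t))
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nn - igraph::vcount(g)))
  igraph::V(g)$kind <- graph$nodes$kind
  igraph::V(g)$x <- graph$nodes$x
  igraph::V(g)$y <- graph$nodes$y
  igraph::V(g)$z <- graph$nodes$z
  g
}

#' Export / import a skeleton graph
#'
#' `"json"` is a lossless round-trip of nodes, branches and per-voxel
#' payload; `"graphml"` writes the node/edge structure via igraph; `"obj"`
#' writes the branch polylines as OBJ `v`/`l` records for 3D viewers.
#'
#' @param graph a `skeleton_graph`.
#' @param path output file.
#' @param format `"json"`, `"graphml"` or `"obj"` (inferred from the
#'   extension when omitted).
#' @export
export_graph <- function(graph, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
    json = {
      out <- list(
        voxel_size = graph$voxel_size, origin = graph$origin,
        nodes = graph$nodes,
        roles = graph$roles, cluster_id = graph$cluster_id,
        voxels = unname(as.matrix(graph$voxels)),
        payload = graph$payload,
        branches = lapply(graph$branches, function(b)
          list(from = b$from, to = b$to, voxels = unname(as.matrix(b$voxels)),
               interior = b$interior, n_voxels = b$n_voxels,
               length = b$length, loop = isTRUE(b$loop))))
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                           na = "null")
    },
    graphml = igraph::write_graph(graph_as_igraph(graph), path,
                                  format = "graphml"),
    obj = {
      con <- file(path, "w")
      on.exit(close(con))
      grid <- voxel_grid(array(TRUE, c(1, 1, 1)), graph$voxel_size,
                         graph$origin)
      off <- 0L
      for (b in graph$branches) {
        pl <- sweep(sweep(as.matrix(b$voxels), 2, 0.5) * graph$voxel_size,
                    2, graph$origin, "+")
        writeLines(sprintf("v %.9g %.9g %.9g", pl[, 1], pl[, 2], pl[, 3]), con)
        if (nrow(pl) > 1L)
          writeLines(paste("l", paste(off + seq_len(nrow(pl)), collapse = " ")),
                     con)
        off <- off + nrow(pl)
      }
    },
    stop("unknown graph export format: ", format))
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format != "json")
    stop("only the JSON graph format supports lossless import")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  branches <- lapply(seq_len(nrow(x$branches)), function(r) {
    b <- x$branches[r, ]
    list(from = b$from, to = b$to,
         voxels = idx_matrix(b$voxels[[1]]),
         interior = unlist(b$interior),
         n_voxels = b$n_voxels, length = b$length, loop = b$loop)
  })
  structure(list(nodes = as.data.frame(x$nodes),
                 branches = branches,
                 voxels = idx_matrix(x$voxels),
                 roles = x$roles, cluster_id = x$cluster_id,
                 payload = if (is.null(x$payload)) NULL else as.data.frame(x$payload),
                 voxel_size = x$voxel_size, origin = x$origin),
            class = "skeleton_graph")
}
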