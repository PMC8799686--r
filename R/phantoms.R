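# Synthetic voxel objects with known ground truth (centerline, radii,
# elliptical ratio, Betti numbers).  Lattice indices are 1-based; the cell
# (i,j,k) has its center at the real-valued lattice point (i,j,k), and maps
# to world coordinates via ((i,j,k) - 0.5) * voxel_size.

new_phantom <- function(occupancy, voxel_size, centerline, radius_profile,
                        betti, kind) {
  occ <- idx_matrix(occupancy)
  if (nrow(occ) == 0L) stop("phantom occupancy is empty")
  structure(
    list(occupancy = occ, voxel_size = voxel_size,
         centerline = centerline, radius_profile = radius_profile,
         betti = as.integer(betti), kind = kind),
    class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom:%s> %d voxels, betti (%d,%d,%d), voxel %.4g m\n",
              x$kind, nrow(x$occupancy), x$betti[1], x$betti[2], x$betti[3],
              x$voxel_size))
  invisible(x)
}

#' Convert a phantom to a padded voxel grid
#'
#' The grid is padded by one void layer on every face; phantom cell
#' `(i,j,k)` becomes grid cell `(i,j,k) + 1`, and the grid origin is
#' `-voxel_size` so that world coordinates agree between the phantom lattice
#' and the grid.
#'
#' @param phantom a `voxel_phantom`.
#' @return a `voxel_grid`.
#' @export
phantom_grid <- function(phantom) {
  idx <- phantom$occupancy + 1L
  dims <- apply(idx, 2, max) + 1L
  voxel_grid(idx, phantom$voxel_size, origin = rep(-phantom$voxel_size, 3),
             dims = dims)
}

# cells of a tube around a straight segment p0 -> p1 (lattice coords),
# membership test supplied per slice-plane displacement
axis_perm <- function(axis) {
  switch(axis, x = c(3L, 2L, 1L), y = c(1L, 3L, 2L), z = c(1L, 2L, 3L),
         stop("axis must be one of 'x', 'y', 'z'"))
}

#' Solid circular cylinder phantom
#'
#' Occupancy is every lattice cell whose center lies within `radius` (in
#' voxel widths) of the axis segment; the ground-truth centerline is the
#' axis cells.  Built along z and permuted to the requested axis.
#'
#' @param radius cylinder radius in voxel widths (>= 0.5).
#' @param length cylinder length in voxels (>= 3).
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param voxel_size voxel edge length in metres (default 1 cm, the scale of
#'   photogrammetric voxelisations of root-sized elements).
#' @return a `voxel_phantom` with betti (1, 0, 0).
#' @export
make_cylinder <- function(radius, length, axis = "z", voxel_size = 0.01) {
  make_elliptical_tube(radius, radius, length, axis, voxel_size,
                       kind = "cylinder")
}

#' Solid elliptical tube phantom
#'
#' Per-slice occupancy is the filled ellipse `(dx/a)^2 + (dy/b)^2 <= 1`
#' around the axis (a along the first in-plane axis).  The ground-truth
#' elliptical ratio is `a / b` at every centerline point.
#'
#' @param a major semi-axis in voxel widths.
#' @param b minor semi-axis in voxel widths (`a >= b`, both >= 0.5).
#' @param length tube length in voxels.
#' @param axis tube axis, one of `"x"`, `"y"`, `"z"`.
#' @param voxel_size voxel edge length in metres.
#' @param kind internal label.
#' @return a `voxel_phantom` with betti (1, 0, 0).
#' @export
make_elliptical_tube <- function(a, b, length, axis = "z", voxel_size = 0.01,
                                 kind = "elliptical_tube") {
  if (!is.finite(a) || !is.finite(b) || b < 0.5 || a <= 0 || length < 3)
    stop("invalid parameters: need a >= b >= 0.5 and length >= 3")
  if (a < b) stop("invalid parameters: major semi-axis a must be >= b")
  ca <- ceiling(a) + 1L; cb <- ceiling(b) + 1L
  ia <- seq_len(2L * ca - 1L); ib <- seq_len(2L * cb - 1L)
  g <- expand.grid(u = ia, v = ib)
  keep <- ((g$u - ca) / a)^2 + ((g$v - cb) / b)^2 <= 1
  sec <- as.matrix(g[keep, , drop = FALSE])
  L <- as.integer(length)
  occ <- cbind(sec[rep(seq_len(nrow(sec)), L), , drop = FALSE],
               rep(seq_len(L), each = nrow(sec)))
  ctr <- cbind(ca, cb, seq_len(L))
  perm <- axis_perm(axis)
  occ <- occ[, perm, drop = FALSE]
  ctr <- ctr[, perm, drop = FALSE]
  new_phantom(occ, voxel_size, centerline = list(ctr),
              radius_profile = cbind(a = rep(a, L), b = rep(b, L)),
              betti = c(1L, 0L, 0L), kind = kind)
}

#' Solid torus phantom
#'
#' An anastomotic loop: cells with
#' `(sqrt(dx^2 + dy^2) - major_radius)^2 + dz^2 <= minor_radius^2`.
#'
#' @param major_radius ring radius in voxel widths.
#' @param minor_radius tube radius in voxel widths
#'   (`major_radius > minor_radius >= 0.5`).
#' @param plane plane of the ring, one of `"xy"`, `"xz"`, `"yz"`.
#' @param voxel_size voxel edge length in metres.
#' @return a `voxel_phantom` with betti (1, 1, 0); the centerline is the
#'   closed ring, ordered by angle.
#' @export
make_torus <- function(major_radius, minor_radius, plane = "xy",
                       voxel_size = 0.01) {
  if (!(major_radius > minor_radius) || minor_radius < 0.5)
    stop("invalid parameters: need major_radius > minor_radius >= 0.5")
  c0 <- ceiling(major_radius + minor_radius) + 1L
  ch <- ceiling(minor_radius) + 1L
  ii <- seq_len(2L * c0 - 1L)
  kk <- seq_len(2L * ch - 1L)
  g <- as.matrix(expand.grid(i = ii, j = ii, k = kk))
  rr <- sqrt((g[, 1] - c0)^2 + (g[, 2] - c0)^2)
  keep <- (rr - major_radius)^2 + (g[, 3] - ch)^2 <= minor_radius^2
  occ <- g[keep, , drop = FALSE]
  # ring centerline: one cell per angle step, ordered, closed
  nphi <- max(64L, ceiling(16 * major_radius))
  phi <- 2 * pi * (seq_len(nphi) - 1L) / nphi
  ring <- cbind(c0 + major_radius * cos(phi), c0 + major_radius * sin(phi),
                rep(as.numeric(ch), nphi))
  perm <- switch(plane, xy = c(1L, 2L, 3L), xz = c(1L, 3L, 2L),
                 yz = c(3L, 1L, 2L), stop("plane must be xy, xz or yz"))
  occ <- occ[, perm, drop = FALSE]
  ring <- ring[, perm, drop = FALSE]
  new_phantom(occ, voxel_size, centerline = list(ring),
              radius_profile = cbind(a = rep(minor_radius, nphi),
                                     b = rep(minor_radius, nphi)),
              betti = c(1L, 1L, 0L), kind = "torus")
}

#' Y-junction phantom
#'
#' A vertical trunk splitting at a single ground-truth junction point into
#' two straight branches tilted by `angles` (degrees from vertical, one to
#' +x, one to -x).
#'
#' @param trunk_radius,branch_radius radii in voxel widths (>= 1).
#' @param angles two branch angles in degrees, each in (0, 90].
#' @param trunk_length,branch_length lengths in voxels.
#' @param voxel_size voxel edge length in metres.
#' @return a `voxel_phantom` with betti (1, 0, 0), three centerline chains
#'   meeting at the junction, and three curve ends.
#' @export
make_y_junction <- function(trunk_radius, branch_radius = trunk_radius,
                            angles = c(35, 35), trunk_length = 12,
                            branch_length = 10, voxel_size = 0.01) {
  if (trunk_radius < 1 || branch_radius < 1)
    stop("invalid parameters: radii must be >= 1")
  if (length(angles) != 2L || any(angles <= 0) || any(angles > 90))
    stop("invalid parameters: branch angles must lie in (0, 90] degrees")
  th <- angles * pi / 180
  dir1 <- c(sin(th[1]), 0, cos(th[1]))
  dir2 <- c(-sin(th[2]), 0, cos(th[2]))
  # branch axes separate by at least one branch diameter at their far ends?
  tip1 <- dir1 * branch_length; tip2 <- dir2 * branch_length
  if (sqrt(sum((tip1 - tip2)^2)) < 2 * branch_radius + 1)
    stop("invalid parameters: branch angles cause the branches to overlap")
  margin <- ceiling(branch_length * max(sin(th)) + branch_radius) + 1L
  cx <- margin + 1L
  cy <- ceiling(max(trunk_radius, branch_radius)) + 1L
  jz <- as.integer(trunk_length) + 1L
  J <- c(cx, cy, jz)
  seg_pts <- function(p0, p1, step = 0.25) {
    L <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, by = step / max(L, step))
    cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
          p0[3] + t * (p1[3] - p0[3]))
  }
  trunk <- seg_pts(c(cx, cy, 1), J)
  br1 <- seg_pts(J, J + dir1 * branch_length)
  br2 <- seg_pts(J, J + dir2 * branch_length)
  zmax <- ceiling(jz + branch_length + branch_radius) + 1L
  g <- as.matrix(expand.grid(i = seq_len(2L * cx), j = seq_len(2L * cy - 1L),
                             k = seq_len(zmax)))
  dmin <- function(pts, samples) {
    # min distance from each cell center to a polyline sample set
    out <- rep(Inf, nrow(pts))
    for (r in seq_len(nrow(samples))) {
      d2 <- (pts[, 1] - samples[r, 1])^2 + (pts[, 2] - samples[r, 2])^2 +
        (pts[, 3] - samples[r, 3])^2
      out <- pmin(out, d2)
    }
    sqrt(out)
  }
  keep <- dmin(g, trunk) <= trunk_radius |
    dmin(g, br1) <= branch_radius | dmin(g, br2) <= branch_radius
  occ <- g[keep, , drop = FALSE]
  nb <- ceiling(branch_length) * 4L
  new_phantom(occ, voxel_size,
              centerline = list(trunk = trunk, branch1 = br1, branch2 = br2),
              radius_profile = cbind(a = c(rep(trunk_radius, nrow(trunk)),
                                           rep(branch_radius, nrow(br1) + nrow(br2))),
                                     b = c(rep(trunk_radius, nrow(trunk)),
                                           rep(branch_radius, nrow(br1) + nrow(br2)))),
              betti = c(1L, 0L, 0L), kind = "y_junction")
}

# ---- surface sampling -------------------------------------------------------

#' Sampling specification for phantom surface clouds
#'
#' @param points_per_unit_area surface point density (points per square
#'   metre).  The default, 10 points per exposed voxel face, mirrors
#'   photogrammetric clouds whose voxel size is chosen so that even sparse
#'   regions have at least one point per voxel (typical regions many more).
#' @param noise_sigma_ratio std. dev. of i.i.d. Gaussian coordinate noise as
#'   a multiple of the voxel size.
#' @param hole_specs list of spherical-cap cutouts, each
#'   `list(center = <unit direction from the phantom centroid>,
#'   angular_radius = <degrees>)`.
#' @param seed integer seed; one explicit seed, single stream, so sampling
#'   is exactly reproducible.
#' @return a `sampling_spec`.
#' @export
sampling_spec <- function(points_per_unit_area = NULL, noise_sigma_ratio = 0,
                          hole_specs = list(), seed = 1L) {
  if (!is.null(points_per_unit_area) && points_per_unit_area <= 0)
    stop("density must be positive")
  if (noise_sigma_ratio < 0) stop("noise_sigma_ratio must be >= 0")
  structure(list(points_per_unit_area = points_per_unit_area,
                 noise_sigma_ratio = noise_sigma_ratio,
                 hole_specs = hole_specs, seed = as.integer(seed)),
            class = "sampling_spec")
}

#' Sample a surface point cloud from a phantom
#'
#' The surface is the set of exposed voxel faces (object cells with a void
#' 6-neighbor) -- what a photogrammetric survey sees.  Points are placed
#' uniformly per face (Poisson counts at the requested density, nudged a
#' hair inside the cell so a noise-free cloud voxelises back onto the
#' phantom lattice), spherical-cap holes are cut, and Gaussian jitter with
#' sigma = `noise_sigma_ratio * voxel_size` is added per coordinate.
#'
#' @param phantom a `voxel_phantom`.
#' @param spec a `sampling_spec`.
#' @return a `point_cloud` in metres.
#' @export
sample_surface_cloud <- function(phantom, spec = sampling_spec()) {
  vs <- phantom$voxel_size
  density <- spec$points_per_unit_area
  if (is.null(density)) density <- 10 / vs^2
  occ <- phantom$occupancy
  dims <- apply(occ, 2, max) + 1L
  A <- array(FALSE, dims)
  A[lin_index(occ, dims)] <- TRUE
  set.seed(spec$seed)
  face_area <- vs^2
  lambda <- density * face_area
  if (lambda < 1) warning("density too low to cover the surface (",
                          signif(lambda, 3), " points per face)")
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  pts <- vector("list", 6L)
  eps <- 1e-4
  for (f in seq_len(6L)) {
    o <- dirs[f, ]
    exposed <- A & !shift3(A, as.integer(o))     # neighbor in +o is void
    cells <- which(exposed, arr.ind = TRUE)
    if (nrow(cells) == 0L) next
    n <- stats::rpois(nrow(cells), lambda)
    tot <- sum(n)
    if (tot == 0L) next
    cell_rep <- cells[rep(seq_len(nrow(cells)), n), , drop = FALSE]
    # in-face uniform offsets; face lies at +0.5*o from the center, pulled
    # eps inward so the point stays inside its own cell
    u <- stats::runif(tot, -0.5, 0.5); v <- stats::runif(tot, -0.5, 0.5)
    ax <- which(o != 0)
    tang <- setdiff(1:3, ax)
    p <- matrix(0, tot, 3)
    p[, ax] <- cell_rep[, ax] + o[ax] * (0.5 - eps)
    p[, tang[1]] <- cell_rep[, tang[1]] + u
    p[, tang[2]] <- cell_rep[, tang[2]] + v
    pts[[f]] <- p
  }
  P <- do.call(rbind, pts)
  if (is.null(P) || nrow(P) == 0L) stop("no surface points sampled")
  # spherical-cap holes, evaluated on the noise-free geometry
  if (length(spec$hole_specs) > 0L) {
    ctr <- colMeans(occ)
    rel <- sweep(P, 2, ctr)
    rn <- sqrt(rowSums(rel^2))
    drop <- rep(FALSE, nrow(P))
    for (h in spec$hole_specs) {
      dirh <- h$center / sqrt(sum(h$center^2))
      ang <- acos(pmin(1, pmax(-1, (rel %*% dirh) / pmax(rn, 1e-12))))
      drop <- drop | (ang < h$angular_radius * pi / 180)
    }
    P <- P[!drop, , drop = FALSE]
    if (nrow(P) == 0L) stop("hole specs removed every sampled point")
  }
  W <- (P - 0.5) * vs
  if (spec$noise_sigma_ratio > 0) {
    W <- W + matrix(stats::rnorm(length(W), 0, spec$noise_sigma_ratio * vs),
                    nrow(W), 3)
  }
  point_cloud(W, label = paste0("phantom:", phantom$kind))
}

#' Serialize a phantom as columnar text plus a JSON sidecar
#'
#' @param phantom a `voxel_phantom`.
#' @param path path for the occupancy table (one `i j k` triple per line);
#'   `<path>.json` receives voxel size, centerline, radius profile and
#'   Betti numbers.
#' @export
write_phantom <- function(phantom, path) {
  utils::write.table(phantom$occupancy, path, row.names = FALSE,
                     col.names = FALSE)
  side <- list(voxel_size = phantom$voxel_size, kind = phantom$kind,
               betti = phantom$betti,
               centerline = lapply(phantom$centerline, function(m)
                 unname(as.matrix(m))),
               radius_profile = unname(as.matrix(phantom$radius_profile)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  occ <- as.matrix(utils::read.table(path))
  cl <- side$centerline
  if (is.matrix(cl)) cl <- list(cl)
  new_phantom(occ, side$voxel_size, cl, side$radius_profile, side$betti,
              side$kind)
}
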