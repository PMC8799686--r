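# End-to-end driver: orientation, voxelisation, denoising, filling,
# thinning, segmentation, reconstruction and reports, with per-step
# instrumentation and provenance.

#' Pipeline configuration
#'
#' @param input path to a point cloud (PLY/PCD/XYZ), or a `point_cloud`.
#' @param format input format override.
#' @param depth octree depth (exactly one of `depth`/`voxel_size`).
#' @param voxel_size voxel edge length in metres.
#' @param orient run PCA orientation first.
#' @param scale optional `c(measured, in_cloud)` reference pair for uniform
#'   scaling.
#' @param fill_list_path optional JSON fill list for the manual
#'   surface-filling step.
#' @param internal_fill fill internal spaces (disable only for debugging).
#' @param reconstruction_mode `"circular"` or `"elliptical"`.
#' @param exposure_index `n` in 1..4 for the reconstruction.
#' @param radius_scale voxel widths per exposure cycle.
#' @param model_path JSON file with an elliptical-ratio model (required for
#'   elliptical mode).
#' @param origin optional fixed voxelisation origin.
#' @param keep_first_tie keep the first component on a denoising tie.
#' @param seed integer seed recorded with the run.
#' @param out_dir optional directory; when given, all artifacts are written
#'   there with a JSON provenance header.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input, format = NULL, depth = NULL,
                            voxel_size = NULL, orient = FALSE, scale = NULL,
                            fill_list_path = NULL, internal_fill = TRUE,
                            reconstruction_mode = "circular",
                            exposure_index = 2L, radius_scale = 1,
                            model_path = NULL, origin = NULL,
                            keep_first_tie = FALSE, seed = 1L,
                            out_dir = NULL) {
  if (is.null(depth) == is.null(voxel_size))
    stop("config must set exactly one of depth / voxel_size")
  if (!reconstruction_mode %in% c("circular", "elliptical"))
    stop("reconstruction_mode must be circular or elliptical")
  if (reconstruction_mode == "elliptical" && is.null(model_path))
    stop("elliptical mode requires a model (set model_path)")
  if (is.character(input) && !file.exists(input))
    stop("input path not resolvable: ", input)
  if (!is.null(fill_list_path) && !file.exists(fill_list_path))
    stop("fill list path not resolvable: ", fill_list_path)
  if (!is.null(model_path) && is.character(model_path) &&
      !file.exists(model_path))
    stop("model path not resolvable: ", model_path)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write an elliptical-ratio model as JSON
#'
#' @param model an `er_model`.
#' @param path JSON path.
#' @export
write_er_model <- function(model, path) {
  jsonlite::write_json(list(slope = model$slope, intercept = model$intercept,
                            r_squared = model$r_squared,
                            predictor = model$predictor),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_er_model
#' @export
read_er_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  r2 <- suppressWarnings(as.numeric(x$r_squared))
  er_model(x$slope, x$intercept, x$predictor,
           if (length(r2) != 1L || is.na(r2)) NA_real_ else r2)
}

#' Write a skeleton as CSV plus JSON header
#'
#' Columns: lattice indices, world coordinates, `I1..I4`, exposed-face
#' count, then the six per-direction exposure iterations.
#'
#' @param skeleton a `skeleton`.
#' @param path CSV path; `<path>.json` receives voxel size, origin, dims
#'   and cycle count.
#' @export
write_skeleton <- function(skeleton, path) {
  df <- cbind(skeleton$voxels, as.data.frame(skeleton$exposure_dirs))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(voxel_size = skeleton$grid$voxel_size,
                            origin = skeleton$grid$origin,
                            dims = dim(skeleton$grid$occ),
                            cycles = skeleton$cycles),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full skeletonisation pipeline
#'
#' Chains the nine processing steps: (1) PCA orientation, (2-3)
#' voxelisation onto a Cartesian lattice, (4) denoising, (5) surface
#' filling from a fill list, (6) internal space filling, (7) thinning with
#' exposure recording, (8) branch/joint segmentation, (9) circular or
#' elliptical volume reconstruction -- plus topology and replication
#' reports.  Deterministic given the config.
#'
#' @param config a `pipeline_config`.
#' @return list of class `pipeline_run`: `grid` (filled), `skeleton`,
#'   `graph`, `reconstruction`, `reports`, `steps` (instrumentation) and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("need a pipeline_config")
  set.seed(config$seed)
  steps <- data.frame(step = character(0), seconds = numeric(0),
                      voxels = integer(0), bytes = numeric(0))
  clock <- function(name, bytes, voxels, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    steps[nrow(steps) + 1L, ] <<- list(name, proc.time()[["elapsed"]] - t0,
                                       as.integer(voxels), as.numeric(bytes))
    res
  }
  cloud <- if (inherits(config$input, "point_cloud")) config$input
           else read_cloud(config$input, config$format)
  in_bytes <- if (is.character(config$input)) file.size(config$input)
              else utils::object.size(cloud$points)
  steps[1L, ] <- list("read", 0, nrow(cloud$points), as.numeric(in_bytes))
  if (config$orient)
    cloud <- clock("orient", in_bytes, nrow(cloud$points),
                   orient_by_pca(cloud))
  if (!is.null(config$scale))
    cloud <- clock("scale", in_bytes, nrow(cloud$points),
                   apply_scale(cloud, config$scale[1], config$scale[2]))
  grid <- clock("voxelize", in_bytes, NA,
                voxelize(cloud, depth = config$depth,
                         voxel_size = config$voxel_size,
                         origin = config$origin))
  steps$voxels[nrow(steps)] <- sum(grid$occ)
  grid <- clock("denoise", in_bytes, NA,
                denoise(grid, keep_first = config$keep_first_tie))
  steps$voxels[nrow(steps)] <- sum(grid$occ)
  if (!is.null(config$fill_list_path))
    grid <- clock("fill_surface", in_bytes, NA,
                  fill_surface(grid, read_fill_list(config$fill_list_path)))
  if (config$internal_fill)
    grid <- clock("fill_internal", in_bytes, NA, fill_internal(grid))
  steps$voxels[nrow(steps)] <- sum(grid$occ)
  skel <- clock("thin", in_bytes, NA, thin(grid))
  steps$voxels[nrow(steps)] <- nrow(skel$voxels)
  graph <- clock("segment", in_bytes, nrow(skel$voxels),
                 segment_branches(skel))
  rec <- clock("reconstruct", in_bytes, NA,
               if (config$reconstruction_mode == "circular")
                 reconstruct_circular(skel, config$exposure_index,
                                      config$radius_scale)
               else
                 reconstruct_elliptical(
                   skel,
                   if (inherits(config$model_path, "er_model")) config$model_path
                   else read_er_model(config$model_path),
                   config$exposure_index, config$radius_scale))
  steps$voxels[nrow(steps)] <- sum(rec$grid$occ)
  reports <- list(topology_input = topology_report(grid),
                  topology_skeleton = topology_report(skel$grid),
                  replication = replication_metrics(grid, rec))
  run <- structure(list(grid = grid, skeleton = skel, graph = graph,
                        reconstruction = rec, reports = reports,
                        steps = steps, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run:\n")
  print(x$steps, digits = 3)
  print(x$reports$topology_skeleton)
  print(x$reports$replication)
  invisible(x)
}

write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  cfg <- run$config
  cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory cloud>"
  cfg$model_path <- if (inherits(cfg$model_path, "er_model"))
    "<in-memory model>" else cfg$model_path
  cfg_json <- p("config.json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")], cfg_json,
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  provenance <- list(
    package = "voxelskel",
    version = as.character(utils::packageVersion("voxelskel")),
    r_version = as.character(getRversion()),
    config_md5 = unname(tools::md5sum(cfg_json)),
    steps = run$steps)
  jsonlite::write_json(provenance, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  write_grid(run$grid, p("grid.txt"))
  write_skeleton(run$skeleton, p("skeleton.csv"))
  export_graph(run$graph, p("graph.json"))
  write_grid(run$reconstruction$grid, p("reconstruction.txt"))
  jsonlite::write_json(list(
    topology_input = unclass(run$reports$topology_input),
    topology_skeleton = unclass(run$reports$topology_skeleton),
    replication = run$reports$replication[
      c("replicated_fraction", "correct_fraction",
        "n_original", "n_reconstructed")]),
    p("reports.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# ---- plotting ---------------------------------------------------------------

#' Plot a skeleton as axis projections
#'
#' Three orthogonal projections of the input occupancy (grey) and the
#' skeleton voxels (colored by `I2`).
#'
#' @param x a `skeleton`.
#' @param grid optional original `voxel_grid` to underlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.skeleton <- function(x, grid = NULL, ...) {
  v <- x$voxels
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  planes <- list(c("i", "j"), c("i", "k"), c("j", "k"))
  cols <- grDevices::hcl.colors(max(v$I2, 1, na.rm = TRUE) + 1L, "viridis")
  for (pl in planes) {
    if (!is.null(grid)) {
      o <- occupied_indices(grid)
      colnames(o) <- c("i", "j", "k")
      graphics::plot(o[, pl[1]], o[, pl[2]], pch = 15, cex = 0.5,
                     col = "grey85", xlab = pl[1], ylab = pl[2],
                     asp = 1, ...)
      graphics::points(v[[pl[1]]], v[[pl[2]]], pch = 15, cex = 0.7,
                       col = cols[pmax(v$I2, 0) + 1L])
    } else {
      graphics::plot(v[[pl[1]]], v[[pl[2]]], pch = 15, cex = 0.7,
                     col = cols[pmax(v$I2, 0) + 1L],
                     xlab = pl[1], ylab = pl[2], asp = 1, ...)
    }
  }
  invisible(x)
}

#' Plot an elliptical-ratio model fit
#'
#' @param x an `er_model`.
#' @param samples optional training data frame (`I1..I4`, `er`) to scatter.
#' @param ... passed to [graphics::plot()].
#' @export
plot.er_model <- function(x, samples = NULL, ...) {
  if (!is.null(samples)) {
    r <- predictor_ratio(samples, x$predictor)
    graphics::plot(r, samples$er, pch = 16, col = "grey40",
                   xlab = x$predictor, ylab = "elliptical ratio", ...)
  } else {
    graphics::plot(NA, xlim = c(1, 5), ylim = c(1, 5),
                   xlab = x$predictor, ylab = "elliptical ratio", ...)
  }
  graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  invisible(x)
}
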