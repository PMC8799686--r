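# Iteration-of-exposure volume reconstruction: circular (step "9a") and
# elliptical (step "9b") cross-sections built out in the global xy plane
# from each skeleton voxel, with radii proportionate to the exposure
# iterations.

exposure_value <- function(skeleton, n) {
  v <- skeleton$voxels
  val <- v[[paste0("I", n)]]
  # voxels with fewer than n exposed faces fall back to their largest
  # recorded exposure (busy junctions)
  for (m in rev(seq_len(4L))) {
    miss <- is.na(val)
    if (!any(miss)) break
    val[miss] <- v[[paste0("I", m)]][miss]
  }
  val[is.na(val)] <- 0L
  val
}

disc_offsets <- function(r) {
  if (r <= 0) return(matrix(0L, 1, 2))
  m <- ceiling(r)
  g <- as.matrix(expand.grid(du = -m:m, dv = -m:m))
  g <- g[g[, 1]^2 + g[, 2]^2 <= r^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  rbind(c(0L, 0L), g[!(g[, 1] == 0L & g[, 2] == 0L), , drop = FALSE])
}

ellipse_offsets <- function(a, b, major_axis = 1L) {
  # semi-axes in voxel widths; major along in-plane axis 1 (x) or 2 (y)
  if (a <= 0 || b <= 0) return(matrix(0L, 1, 2))
  ma <- ceiling(a); mb <- ceiling(b)
  if (major_axis == 1L) {
    g <- as.matrix(expand.grid(du = -ma:ma, dv = -mb:mb))
    keep <- (g[, 1] / a)^2 + (g[, 2] / b)^2 <= 1
  } else {
    g <- as.matrix(expand.grid(du = -mb:mb, dv = -ma:ma))
    keep <- (g[, 1] / b)^2 + (g[, 2] / a)^2 <= 1
  }
  g <- g[keep, , drop = FALSE]
  storage.mode(g) <- "integer"
  rbind(c(0L, 0L), g[!(g[, 1] == 0L & g[, 2] == 0L), , drop = FALSE])
}

paint_sections <- function(skeleton, per_voxel_offsets) {
  d <- dim(skeleton$grid$occ)
  occ <- array(FALSE, d)
  v <- skeleton$voxels
  for (r in seq_len(nrow(v))) {
    off <- per_voxel_offsets[[r]]
    ii <- v$i[r] + off[, 1]; jj <- v$j[r] + off[, 2]
    ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2]
    occ[cbind(ii[ok], jj[ok], v$k[r])] <- TRUE
  }
  occ[cbind(v$i, v$j, v$k)] <- TRUE        # skeleton always contained
  grid_replace_occ(skeleton$grid, occ)
}

new_reconstruction <- function(grid, mode, n, radius_scale, extra = list()) {
  structure(c(list(grid = grid, mode = mode, exposure_index_used = n,
                   radius_scale = radius_scale), extra),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction_result> %s sections from I%d, %d voxels (scale %.3g)\n",
              x$mode, x$exposure_index_used, sum(x$grid$occ), x$radius_scale))
  invisible(x)
}

#' Circular volume reconstruction from iterations of exposure
#'
#' For each skeleton voxel, every cell of its horizontal (xy) section plane
#' within `radius_scale * I_n` voxel widths of the voxel center becomes
#' object (the skeleton voxel itself always included).  Because
#' `I1 <= I2 <= I3 <= I4` per voxel, occupancy is non-decreasing in `n`:
#' I1 reconstructions are conservative, I4 generous.
#'
#' @param skeleton a `skeleton` with exposure data.
#' @param n which exposure iteration to use (1..4; default 2, the best
#'   compromise between replication and correctness).
#' @param radius_scale voxel widths of section radius per exposure cycle
#'   (default 1: one thinning cycle eats about one voxel shell).
#' @return a `reconstruction_result`.
#' @export
reconstruct_circular <- function(skeleton, n = 2L, radius_scale = 1) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > 4L)
    stop("exposure index n must be in 1..4")
  val <- exposure_value(skeleton, n)
  radii <- radius_scale * val
  cache <- new.env(parent = emptyenv())
  offs <- lapply(radii, function(r) {
    key <- format(r)
    got <- cache[[key]]
    if (is.null(got)) cache[[key]] <- got <- disc_offsets(r)
    got
  })
  new_reconstruction(paint_sections(skeleton, offs), "circular", n,
                     radius_scale)
}

# ---- elliptical-ratio model -------------------------------------------------

#' Construct an elliptical-ratio model directly from coefficients
#'
#' `ER = slope * ratio + intercept`, where the ratio is an exposure
#' iteration ratio such as `I4:I1`.  Predictions are clamped to `>= 1`
#' (an elliptical ratio below 1 is meaningless) and capped (the linear
#' model can extrapolate absurdly on outlier ratios).
#'
#' @param slope,intercept model coefficients.
#' @param predictor which ratio the model maps (`"I4:I1"`, `"I3:I1"`,
#'   `"I2:I1"` or `"mean"` for `(I2+I3+I4)/3 : I1`).
#' @param r_squared optional fit quality in `[0, 1]`.
#' @return an object of class `er_model`.
#' @export
er_model <- function(slope, intercept, predictor = "I4:I1",
                     r_squared = NA_real_) {
  if (!predictor %in% c("I2:I1", "I3:I1", "I4:I1", "mean"))
    stop("unknown predictor: ", predictor)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 predictor = predictor, r_squared = r_squared,
                 all_r_squared = NULL, n = NA_integer_),
            class = "er_model")
}

#' @export
print.er_model <- function(x, ...) {
  cat(sprintf("elliptical-ratio model: ER = %.4f * (%s) + %.4f  (R^2 %s, n %s)\n",
              x$slope, x$predictor, x$intercept,
              ifelse(is.na(x$r_squared), "?", sprintf("%.4f", x$r_squared)),
              ifelse(is.na(x$n), "?", x$n)))
  if (!is.null(x$all_r_squared)) {
    cat("candidate predictors (R^2):\n")
    print(round(x$all_r_squared, 4))
  }
  invisible(x)
}

#' @export
coef.er_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

predictor_ratio <- function(samples, predictor) {
  I1 <- samples$I1
  switch(predictor,
    "I2:I1" = samples$I2 / I1,
    "I3:I1" = samples$I3 / I1,
    "I4:I1" = samples$I4 / I1,
    "mean"  = (samples$I2 + samples$I3 + samples$I4) / 3 / I1,
    stop("unknown predictor: ", predictor))
}

#' Predict elliptical ratios from exposure ratios
#'
#' @param object an `er_model`.
#' @param ratio numeric vector of exposure-iteration ratios, or a data
#'   frame with columns `I1..I4` from which the model's predictor ratio is
#'   computed.
#' @param cap upper bound on the predicted ratio (default 6).
#' @param ... unused.
#' @return predicted elliptical ratios, clamped to `[1, cap]`.
#' @export
predict.er_model <- function(object, ratio, cap = 6, ...) {
  if (is.data.frame(ratio)) ratio <- predictor_ratio(ratio, object$predictor)
  pmin(pmax(object$slope * ratio + object$intercept, 1), cap)
}

#' Fit the elliptical-ratio regression
#'
#' Ordinary least squares of the true elliptical ratio on an exposure
#' iteration ratio, the step-"9b" link between thinning dynamics and
#' section shape: in a flattened cross-section the minor axis is eaten
#' early (small `I1`) and the major axis late (large `I4`), so `I4:I1`
#' tracks the axis ratio.  R-squared is reported for all candidate
#' predictors so the best can be selected.
#'
#' @param samples data frame with columns `I1`, `I2`, `I3`, `I4` and `er`
#'   (true elliptical ratio); rows with `I1 == 0` are dropped (the ratio
#'   is undefined).
#' @param predictor which ratio to fit (default `"I4:I1"`).
#' @return an `er_model` with slope, intercept, `r_squared`,
#'   `all_r_squared` and the sample count.
#' @export
fit_ellipse_ratio_model <- function(samples, predictor = "I4:I1") {
  samples <- as.data.frame(samples)
  need <- c("I1", "I2", "I3", "I4", "er")
  if (!all(need %in% names(samples)))
    stop("samples must have columns I1..I4 and er")
  samples <- samples[!is.na(samples$I1) & samples$I1 > 0 &
                       !is.na(samples$I4), , drop = FALSE]
  if (nrow(samples) < 3L) stop("need at least 3 samples with I1 > 0")
  fits <- list()
  r2 <- c()
  for (p in c("I2:I1", "I3:I1", "I4:I1", "mean")) {
    x <- predictor_ratio(samples, p)
    if (stats::var(x) < 1e-12) {
      if (p == predictor)
        stop("degenerate fit: predictor ", p, " has zero variance")
      r2[p] <- NA_real_
      next
    }
    fit <- stats::lm(samples$er ~ x)
    fits[[p]] <- fit
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((samples$er - mean(samples$er))^2)
    r2[p] <- if (tss < 1e-12) as.numeric(rss < 1e-12) else 1 - rss / tss
  }
  fit <- fits[[predictor]]
  out <- er_model(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  predictor = predictor,
                  r_squared = max(0, min(1, r2[[predictor]])))
  out$all_r_squared <- r2
  out$n <- nrow(samples)
  out
}

#' Collect exposure/elliptical-ratio training samples from a skeleton
#'
#' Convenience helper for building the regression input: the skeleton's
#' per-voxel `I1..I4` paired with the known elliptical ratio of the
#' phantom it came from.
#'
#' @param skeleton a `skeleton`.
#' @param true_er the ground-truth elliptical ratio.
#' @return data frame with columns `I1..I4`, `er`.
#' @export
exposure_samples <- function(skeleton, true_er) {
  v <- skeleton$voxels
  data.frame(I1 = v$I1, I2 = v$I2, I3 = v$I3, I4 = v$I4,
             er = rep(true_er, nrow(v)))
}

#' Elliptical volume reconstruction
#'
#' Like [reconstruct_circular()], but each section is an axis-aligned
#' ellipse whose axis ratio is predicted from the voxel's exposure ratios
#' by an [er_model].  For `n` in 1..2 the minor semi-axis is
#' `radius_scale * I_n` and the major axis is enlarged by the predicted
#' ratio; for `n` in 3..4 the major semi-axis is `radius_scale * I_n` and
#' the minor axis is reduced.  The major-axis direction is the in-plane
#' cardinal direction whose opposing faces were exposed latest (never
#' exposed counts as latest); ties go to x.  Voxels with `I1 = 0` but
#' nonzero `I_n` have an undefined ratio and fall back to circular
#' sections of radius `radius_scale * I_n` (counted in the result).
#'
#' @param skeleton a `skeleton` with exposure data.
#' @param model an `er_model`.
#' @param n exposure index 1..4 (default 1; with the elliptical correction
#'   the conservative I1 sections regain most of the volume).
#' @param radius_scale voxel widths per exposure cycle.
#' @param cap cap on predicted elliptical ratios.
#' @return a `reconstruction_result` (field `n_fallback_circular` counts
#'   the fallback voxels).
#' @export
reconstruct_elliptical <- function(skeleton, model, n = 1L, radius_scale = 1,
                                   cap = 6) {
  if (!inherits(model, "er_model")) stop("model must be an er_model")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > 4L)
    stop("exposure index n must be in 1..4")
  v <- skeleton$voxels
  val <- exposure_value(skeleton, n)
  I1 <- v$I1; I1[is.na(I1)] <- 0L
  ratio <- predictor_ratio(data.frame(I1 = I1, I2 = exposure_value(skeleton, 2),
                                      I3 = exposure_value(skeleton, 3),
                                      I4 = exposure_value(skeleton, 4)),
                           model$predictor)
  er <- predict(model, ratio, cap = cap)
  fallback <- I1 == 0 & val > 0
  # major-axis direction: the in-plane axis whose opposing faces stayed
  # buried longest (NA = never exposed = latest); ties toward x
  E <- skeleton$exposure_dirs
  late <- function(a, b) {
    m <- pmax(ifelse(is.na(a), Inf, a), ifelse(is.na(b), Inf, b))
    m
  }
  lx <- late(E[, "xplus"], E[, "xminus"])
  ly <- late(E[, "yplus"], E[, "yminus"])
  major_axis <- ifelse(ly > lx, 2L, 1L)
  offs <- vector("list", nrow(v))
  for (r in seq_len(nrow(v))) {
    if (fallback[r]) {
      offs[[r]] <- disc_offsets(radius_scale * val[r])
    } else if (val[r] == 0) {
      offs[[r]] <- matrix(0L, 1, 2)
    } else if (n <= 2L) {
      minor <- radius_scale * val[r]
      offs[[r]] <- ellipse_offsets(er[r] * minor, minor, major_axis[r])
    } else {
      major <- radius_scale * val[r]
      offs[[r]] <- ellipse_offsets(major, major / er[r], major_axis[r])
    }
  }
  if (any(fallback))
    message(sum(fallback), " voxel(s) with I1 = 0 fell back to circular sections")
  new_reconstruction(paint_sections(skeleton, offs), "elliptical", n,
                     radius_scale,
                     extra = list(model = model,
                                  n_fallback_circular = sum(fallback)))
}
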