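#' Control parameters for curve fitting and scoring
#'
#' Collects every tunable of the pipeline with its default. Units: bandwidths,
#' step sizes and tolerances are in mapping-space score units (the defaults
#' are expressed as fractions of the data range / bandwidth, so they adapt to
#' scale automatically).
#'
#' @param scale reference-normalization denominator, `"variance"` (literal
#'   default) or `"sd"`.
#' @param variance_filter_quantile gene-variance quantile below which genes
#'   are removed (default 0.25).
#' @param pc_excess_fraction tumor-over-normal variance excess for keeping a
#'   principal component (default 0.10).
#' @param component_rule component-selection reading, `"normal_total"`
#'   (default), `"contiguous"` or `"count"`; see [build_mapping_space()].
#' @param min_genes_per_set minimum genes of a set that must be present
#'   (default 2).
#' @param pc_fallback_variance cumulative-variance target when no reference
#'   samples exist (default 0.80).
#' @param bandwidth_fraction kernel bandwidth as a fraction of the
#'   per-dimension range (default 0.10).
#' @param step_size LPC step t_0; `NULL` (default) takes one kernel
#'   bandwidth along the travel direction per iteration.
#' @param tol convergence threshold on centers of mass; `NULL` means
#'   `1e-3 * mean(h)`.
#' @param max_iter iteration cap per direction; `NULL` means 150.
#' @param angle_penalty direction blending weight in `[0, 1]` (default 1,
#'   i.e. off).
#' @param boundary_frac kernel-mass fraction defining the data-cloud boundary
#'   (default 0.001).
#' @param boundary_correction shrink the bandwidth near the data-cloud edge
#'   so centers reach the extremes (see [fit_lpc()]); default TRUE.
#' @param two_sided grow the curve in both directions; `NULL` (default)
#'   resolves to FALSE when a reference start exists and TRUE for mean-shift
#'   starts.
#' @param grid_per_interval arc-table density (default 50).
#' @param projection_refine refine projections within the best grid cell?
#' @param projection_extend project boundary samples onto the end-tangent
#'   extensions?
#' @param normalize BPS normalization mode, `"minmax"` or `"clamp_minmax"`.
#' @param case_insensitive match gene symbols case-insensitively?
#' @param cv_nfolds folds for the internal Cox lambda cross-validation
#'   (default 5).
#' @return A named list of class `lpc_control`.
#' @export
lpc_control <- function(scale = "variance",
                        variance_filter_quantile = 0.25,
                        pc_excess_fraction = 0.10,
                        component_rule = "normal_total",
                        min_genes_per_set = 2L,
                        pc_fallback_variance = 0.80,
                        bandwidth_fraction = 0.10,
                        step_size = NULL,
                        tol = NULL,
                        max_iter = NULL,
                        angle_penalty = 1,
                        boundary_frac = 0.001,
                        boundary_correction = TRUE,
                        two_sided = NULL,
                        grid_per_interval = 50L,
                        projection_refine = TRUE,
                        projection_extend = TRUE,
                        normalize = "minmax",
                        case_insensitive = FALSE,
                        cv_nfolds = 5L) {
  structure(list(
    scale = match.arg(scale, c("variance", "sd")),
    variance_filter_quantile = variance_filter_quantile,
    pc_excess_fraction = pc_excess_fraction,
    component_rule = match.arg(component_rule,
                               c("normal_total", "contiguous", "count")),
    min_genes_per_set = as.integer(min_genes_per_set),
    pc_fallback_variance = pc_fallback_variance,
    bandwidth_fraction = bandwidth_fraction,
    step_size = step_size, tol = tol, max_iter = max_iter,
    angle_penalty = angle_penalty, boundary_frac = boundary_frac,
    boundary_correction = isTRUE(boundary_correction),
    two_sided = two_sided,
    grid_per_interval = as.integer(grid_per_interval),
    projection_refine = isTRUE(projection_refine),
    projection_extend = isTRUE(projection_extend),
    normalize = match.arg(normalize, c("minmax", "clamp_minmax")),
    case_insensitive = isTRUE(case_insensitive),
    cv_nfolds = as.integer(cv_nfolds)),
    class = "lpc_control")
}

#' Fit a local principal curve to a point cloud
#'
#' The core estimator: starting from the reference centroid (or a density
#' mode found by mean shift), the bottom-up LPC iteration alternates
#' kernel-weighted local centers of mass and local first eigenvectors through
#' the data cloud; the recorded centers are interpolated by natural cubic
#' splines, reparameterized by arc length, anchored at the starting point's
#' projection, and every data point is projected onto the curve to yield its
#' signed projection index.
#'
#' @param x numeric matrix of points (rows); typically mapping-space scores.
#' @param start explicit starting point, or `NULL`.
#' @param reference logical/integer index of reference rows used to place the
#'   start when `start` is `NULL`; with neither, a mean-shift mode is used.
#' @param control an [lpc_control()] list.
#' @param init_dir optional initial direction for the first traversal.
#' @return An object of class `lpc` with components `centers`, `curve`
#'   (the `lpc_curve`), `start`, `bandwidth`, `stop_reason`, `projections`
#'   (data.frame of per-point `t` and `distance`), `control`, `call`.
#' @seealso [predict.lpc()], [fitted.lpc()], [residuals.lpc()], [plot.lpc()]
#' @examples
#' set.seed(1)
#' th <- sort(runif(150, 0, pi))
#' pts <- cbind(cos(th), sin(th)) + matrix(rnorm(300, sd = 0.05), ncol = 2)
#' fit <- lpc(pts, start = c(1, 0))
#' fit
#' head(fitted(fit))
#' @export
lpc <- function(x, start = NULL, reference = NULL, control = lpc_control(),
                init_dir = NULL) {
  cl <- match.call()
  x <- as.matrix(x)
  h <- lpc_bandwidth(x, control$bandwidth_fraction)
  anchored <- !is.null(start) ||
    (!is.null(reference) && (!is.logical(reference) || any(reference)))
  x0 <- start %||% choose_start(x, reference, h)
  two_sided <- control$two_sided %||% !anchored
  if (is.null(init_dir) && anchored && !two_sided) {
    ## one-sided growth from a reference anchor must head into the data
    ## cloud; the eigenvector's default sign is arbitrary with respect to it
    g0 <- local_first_eigenvector(x0, x, h)
    towards <- colMeans(x) - x0
    if (sum(g0 * towards) < 0) g0 <- -g0
    init_dir <- g0
  }
  path <- fit_lpc(x, x0, h,
                  step = control$step_size, tol = control$tol,
                  max_iter = control$max_iter,
                  angle_penalty = control$angle_penalty,
                  boundary_frac = control$boundary_frac,
                  two_sided = two_sided, init_dir = init_dir,
                  boundary_correction = control$boundary_correction)
  curve <- parameterize_curve(path$centers, control$grid_per_interval)
  curve <- set_origin(curve, x0)
  pr <- project_lpc(curve, x, control)
  structure(list(centers = path$centers, curve = curve, start = x0,
                 bandwidth = h, step_size = path$step_size,
                 stop_reason = path$stop_reason, two_sided = two_sided,
                 projections = pr, control = control, call = cl),
            class = "lpc")
}

project_lpc <- function(curve, x, control = lpc_control()) {
  x <- as.matrix(x)
  ## batch nearest-grid-point search: ||x_i - p_j||^2 expanded as
  ## |x|^2 - 2 x p' + |p|^2, then per-point refinement in the best cell
  g <- curve$points
  d2 <- outer(rowSums(x^2), rowSums(g^2), "+") - 2 * tcrossprod(x, g)
  best <- max.col(-d2, ties.method = "first")
  out <- lapply(seq_len(nrow(x)), function(i)
    project_point(curve, x[i, ],
                  refine = control$projection_refine,
                  extend = control$projection_extend,
                  .best = best[i], .best_d2 = d2[i, best[i]]))
  data.frame(t = vapply(out, `[[`, 0, "t"),
             distance = vapply(out, `[[`, 0, "distance"),
             row.names = rownames(x))
}

#' @export
print.lpc <- function(x, ...) {
  cat("Local principal curve\n")
  cat(sprintf("  points: %d in %d dimension(s)\n",
              nrow(x$projections), x$curve$p))
  cat(sprintf("  centers: %d   arc length: %.4g   step: %s\n",
              nrow(x$centers), arc_length(x$curve),
              if (is.na(x$step_size)) "adaptive" else format(x$step_size, digits = 4)))
  cat(sprintf("  stop: %s\n",
              paste(names(x$stop_reason), x$stop_reason,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
summary.lpc <- function(object, ...) {
  res <- object$projections$distance
  structure(list(fit = object,
                 arc_length = arc_length(object$curve),
                 distance_summary = summary(res),
                 t_range = range(object$projections$t)),
            class = "summary.lpc")
}

#' @export
print.summary.lpc <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  projection index range: [%.4g, %.4g]\n",
              x$t_range[1], x$t_range[2]))
  cat("  distance to curve:\n")
  print(x$distance_summary)
  invisible(x)
}

#' Project new points onto a fitted local principal curve
#'
#' @param object an `lpc` fit.
#' @param newdata numeric matrix of points (rows); defaults to the training
#'   points.
#' @param ... unused.
#' @return data.frame with columns `t` (signed projection index relative to
#'   the curve origin) and `distance`.
#' @export
predict.lpc <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$projections)
  project_lpc(object$curve, newdata, object$control)
}

#' @export
fitted.lpc <- function(object, ...) {
  setNames(object$projections$t, rownames(object$projections))
}

#' @export
residuals.lpc <- function(object, ...) {
  setNames(object$projections$distance, rownames(object$projections))
}

#' Plot a fitted local principal curve
#'
#' Scatter of the first two dimensions with the fitted curve and starting
#' point overlaid (1-D fits are plotted against the projection index).
#'
#' @param x an `lpc` fit.
#' @param dims which two dimensions to draw (default `c(1, 2)`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lpc <- function(x, dims = c(1, 2), ...) {
  pts <- x$curve$points
  if (x$curve$p == 1L) {
    plot(x$projections$t, rep(0, nrow(x$projections)),
         xlab = "projection index t", ylab = "", yaxt = "n", ...)
    return(invisible(x))
  }
  dims <- dims[1:2]
  ## reconstruct the training cloud from projections is not possible; draw
  ## the curve against the centers instead
  plot(x$centers[, dims[1]], x$centers[, dims[2]],
       xlab = sprintf("dim %d", dims[1]), ylab = sprintf("dim %d", dims[2]),
       type = "p", pch = 16, cex = 0.5, ...)
  lines(pts[, dims[1]], pts[, dims[2]], col = "red3", lwd = 2)
  points(x$start[dims[1]], x$start[dims[2]], pch = 8, col = "blue3", cex = 1.2)
  invisible(x)
}
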