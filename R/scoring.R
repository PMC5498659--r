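#' Normalize projection indices to biological process scores
#'
#' `minmax` maps the indices linearly onto `[0, 1]`. `clamp_minmax` first sets
#' negative indices (samples projecting "behind" the reference origin) to 0
#' and then divides by the maximum, preserving the reference-relative
#' semantics. Constant vectors normalize to all zeros.
#'
#' @param t numeric vector of projection indices.
#' @param mode `"minmax"` (default) or `"clamp_minmax"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_indices <- function(t, mode = c("minmax", "clamp_minmax")) {
  mode <- match.arg(mode)
  if (any(!is.finite(t))) abort_argument("projection indices must be finite")
  if (mode == "clamp_minmax") t <- pmax(t, 0)
  rng <- range(t)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(t)))
  if (mode == "clamp_minmax") t / rng[2] else (t - rng[1]) / (rng[2] - rng[1])
}

## Orientation of the raw projection indices. With a reference anchor the
## curve already grows from the normals into the tumors. Without one the sign
## of t is unidentifiable from the data (reflecting the latent direction is a
## symmetry), so we orient t to increase with the per-sample mean normalized
## expression over the set's genes -- "higher score, larger overall deviation".
orient_indices <- function(t, expr_values, genes, anchored) {
  if (anchored) return(t)
  meanexpr <- colMeans(expr_values[genes, , drop = FALSE])
  rho <- suppressWarnings(cor(t, meanexpr, method = "spearman"))
  if (is.finite(rho) && rho < 0) -t else t
}

#' Score one biological process
#'
#' Runs the per-process chain on an already normalized and variance-filtered
#' expression matrix: mapping space, starting point (reference centroid or
#' mean-shift mode), local principal curve, arc-length parameterization,
#' origin at the starting point's projection, projection of every sample, and
#' normalization of the indices to `[0, 1]`.
#'
#' @param expr a normalized [expression_matrix].
#' @param genes character vector of the process's gene symbols.
#' @param name process name.
#' @param control an [lpc_control()] list.
#' @return List with `bps` (named score vector over samples), `meta`
#'   (one-row data.frame: process, k, n_centers, n_genes, stop reasons,
#'   constant flag) and `fit` (the underlying `lpc` object).
#' @export
score_process <- function(expr, genes, name = "geneset",
                          control = lpc_control()) {
  if (control$case_insensitive) {
    idx <- match(toupper(genes), toupper(rownames(expr$values)))
    genes <- rownames(expr$values)[idx[!is.na(idx)]]
  }
  ms <- build_mapping_space(expr, genes, name,
                            excess_fraction = control$pc_excess_fraction,
                            component_rule = control$component_rule,
                            min_genes = control$min_genes_per_set,
                            fallback_variance = control$pc_fallback_variance)
  anchored <- any(ms$is_reference)
  ctrl <- control
  if (is.null(ctrl$two_sided)) ctrl$two_sided <- !anchored
  fit <- lpc(ms$scores,
             reference = if (anchored) ms$is_reference else NULL,
             control = ctrl)
  t_raw <- fit$projections$t
  t_raw <- orient_indices(t_raw, expr$values, ms$genes_used, anchored)
  bps <- normalize_indices(t_raw, control$normalize)
  constant <- diff(range(t_raw)) <= 0
  list(bps = setNames(bps, colnames(expr$values)),
       meta = data.frame(process = name, k = ms$k,
                         n_centers = nrow(fit$centers),
                         n_genes = length(ms$genes_used),
                         stop_reason = paste(fit$stop_reason, collapse = "/"),
                         constant = constant,
                         stringsAsFactors = FALSE),
       fit = fit)
}

#' Score all biological processes: the expression-to-BPS pipeline
#'
#' Normalizes expression against the reference samples (z-scores without
#' references), removes low-variance genes, and scores every gene set
#' independently with [score_process()]. Sets with too few surviving genes or
#' a degenerate curve are skipped with their reason recorded.
#'
#' @param expr an [expression_matrix] (raw; normalization is applied here).
#' @param genesets a [gene_sets] collection.
#' @param control an [lpc_control()] list.
#' @return An object of class `bps`: list with `values`
#'   (processes x samples matrix in `[0, 1]`), `meta` (per-process
#'   data.frame), `skipped` (named character of skip reasons) and `control`.
#' @examples
#' coh <- simulate_cohort(n_tumor = 60, n_normal = 10, n_processes = 3,
#'                        seed = 1)
#' fit <- bps_score(coh$expression, coh$genesets)
#' fit$values[, 1:4]
#' @export
bps_score <- function(expr, genesets, control = lpc_control()) {
  norm <- normalize_expression(expr, scale = control$scale)
  filt <- filter_low_variance(norm, control$variance_filter_quantile)
  rows <- list()
  meta <- list()
  skipped <- character()
  for (nm in names(genesets)) {
    res <- tryCatch(
      score_process(filt, genesets[[nm]], nm, control),
      lpcscore_skip = function(e) conditionMessage(e),
      lpcscore_degenerate = function(e) conditionMessage(e))
    if (is.character(res)) {
      warning(sprintf("skipped process '%s': %s", nm, res))
      skipped[nm] <- res
    } else {
      rows[[nm]] <- res$bps
      meta[[nm]] <- res$meta
    }
  }
  if (!length(rows))
    abort(paste0("all processes were skipped: ",
                 paste(names(skipped), skipped, sep = ": ", collapse = "; ")),
          "lpcscore_pipeline_error")
  values <- do.call(rbind, rows)
  structure(list(values = values, meta = do.call(rbind, meta),
                 skipped = skipped, control = control),
            class = "bps")
}

#' @export
print.bps <- function(x, ...) {
  cat(sprintf("BPS matrix: %d process(es) x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$skipped))
    cat(sprintf("  skipped: %s\n", paste(names(x$skipped), collapse = ", ")))
  invisible(x)
}

#' @export
summary.bps <- function(object, ...) {
  cat(sprintf("BPS matrix: %d process(es) x %d samples\n",
              nrow(object$values), ncol(object$values)))
  print(object$meta, row.names = FALSE)
  invisible(object)
}
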