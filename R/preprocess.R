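#' Normalize expression against reference samples
#'
#' When reference (normal) samples exist, every value is centered by the
#' gene's reference mean and divided by the gene's reference variance
#' (the default; `scale = "sd"` divides by the standard deviation instead).
#' The same transform is applied to tumor and reference samples so both can be
#' embedded in one mapping space. Without reference samples, genes are
#' z-scored across all samples. Either way a normalized value measures how
#' far a sample deviates from the baseline on that gene's scale.
#'
#' Genes whose reference variance is zero (or whose overall variance is zero
#' in the z-score fallback) are dropped with a warning: the division is
#' undefined for them.
#'
#' @param expr an [expression_matrix].
#' @param scale `"variance"` (default) or `"sd"`: the denominator used when
#'   reference samples exist.
#' @return A normalized [expression_matrix] with the same reference labels.
#' @export
normalize_expression <- function(expr, scale = c("variance", "sd")) {
  scale <- match.arg(scale)
  v <- expr$values
  ref <- expr$is_reference
  if (any(ref) && sum(ref) >= 2L) {
    rv <- v[, ref, drop = FALSE]
    mu <- rowMeans(rv)
    s2 <- apply(rv, 1L, var)
    denom <- if (scale == "variance") s2 else sqrt(s2)
    bad <- !is.finite(denom) | denom <= 0
    if (any(bad)) {
      warning(sprintf("dropped %d gene(s) with zero reference variance", sum(bad)))
      if (all(bad)) abort_argument("every gene has zero reference variance")
      v <- v[!bad, , drop = FALSE]
      mu <- mu[!bad]; denom <- denom[!bad]
    }
    v <- (v - mu) / denom
  } else {
    if (any(ref)) warning("a single reference sample cannot define a variance; falling back to z-scores")
    mu <- rowMeans(v)
    s <- apply(v, 1L, sd)
    bad <- !is.finite(s) | s <= 0
    if (any(bad)) {
      warning(sprintf("dropped %d constant gene(s)", sum(bad)))
      if (all(bad)) abort_argument("every gene is constant")
      v <- v[!bad, , drop = FALSE]
      mu <- mu[!bad]; s <- s[!bad]
    }
    v <- (v - mu) / s
  }
  expression_matrix(v, reference = names(ref)[ref])
}

#' Filter out low-variance genes
#'
#' Removes genes whose variance across all samples is strictly below the
#' given empirical quantile of all gene variances (linear-interpolation
#' quantile; strict `<` so that with tied variances nothing is removed).
#'
#' @param expr an [expression_matrix] (normally after
#'   [normalize_expression()]).
#' @param quantile variance quantile below which genes are removed;
#'   default 0.25.
#' @return The filtered [expression_matrix], gene order preserved.
#' @export
filter_low_variance <- function(expr, quantile = 0.25) {
  if (!is_scalar_number(quantile) || quantile < 0 || quantile > 1)
    abort_argument("`quantile` must be a number in [0, 1]")
  if (ncol(expr$values) < 2L) abort_argument("need >= 2 samples to estimate variances")
  vars <- apply(expr$values, 1L, var)
  thr <- stats::quantile(vars, probs = quantile, names = FALSE, type = 7)
  keep <- !(vars < thr)
  if (!any(keep)) abort("variance filter removed every gene", "lpcscore_pipeline_error")
  ref <- expr$is_reference
  expression_matrix(expr$values[keep, , drop = FALSE],
                    reference = names(ref)[ref])
}

#' Build the PCA mapping space of one gene set
#'
#' Fits a PCA on the (normalized) expression of the set's genes over all
#' samples and keeps the leading components along which the tumor-score
#' variance exceeds the variability seen in the normal samples by more than
#' `excess_fraction`, scanned in order of decreasing eigenvalue, stopped at
#' the first failure, with a floor of one component. Under the default
#' `component_rule = "normal_total"` a component qualifies when its tumor
#' variance exceeds `(1 + excess_fraction)` times the *total* normal-score
#' variance summed over components -- a comparison that is robust to the
#' systematic inflation of per-component tumor variance produced by fitting
#' the PCA on the tumor-dominated pooled sample (on pure-noise components
#' that inflation alone is typically 1.2-2x, so a per-component comparison
#' over-selects at any noise level). The per-component readings remain
#' available as `"contiguous"` (stop at the first failing component) and
#' `"count"` (keep all qualifying components). Without reference samples the
#' rule degenerates and the smallest number of components explaining at least
#' `fallback_variance` of the total variance is kept instead.
#'
#' Principal-axis signs are fixed so that each loading vector's
#' largest-magnitude entry is positive, making the embedding deterministic.
#'
#' @param expr an [expression_matrix] (normalized).
#' @param genes character vector of the set's gene symbols.
#' @param name process name carried into the result.
#' @param excess_fraction tumor-over-normal variance excess required to keep a
#'   component (default 0.10, i.e. v_tumor > 1.1 * v_normal).
#' @param component_rule `"normal_total"` (default), `"contiguous"` or
#'   `"count"`; see Details.
#' @param min_genes minimum number of the set's genes that must be present
#'   (default 2); below it the process is skipped with a condition.
#' @param fallback_variance cumulative variance target used when no reference
#'   samples exist (default 0.80).
#' @return An object of class `mapping_space`: list with `process`, `scores`
#'   (samples x k), `loadings` (genes x k), `center`, `k`,
#'   `component_variances_tumor`, `component_variances_normal`,
#'   `is_reference`, `genes_used`.
#' @export
build_mapping_space <- function(expr, genes, name = "geneset",
                                excess_fraction = 0.10,
                                component_rule = c("normal_total",
                                                   "contiguous", "count"),
                                min_genes = 2L,
                                fallback_variance = 0.80) {
  component_rule <- match.arg(component_rule)
  present <- intersect(genes, rownames(expr$values))
  if (length(present) < min_genes)
    abort(sprintf("gene set '%s': only %d of %d genes present (need >= %d)",
                  name, length(present), length(genes), min_genes),
          "lpcscore_skip")
  n <- ncol(expr$values)
  if (n < 3L) abort_argument("need >= 3 samples to build a mapping space")
  x <- t(expr$values[present, , drop = FALSE])   # samples x genes
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ## deterministic axis orientation
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ref <- expr$is_reference
  kmax <- min(length(present), n - 1L, ncol(pc$x))
  vt <- vn <- rep(NA_real_, kmax)
  if (any(ref) && sum(ref) >= 2L && sum(!ref) >= 2L) {
    vt <- apply(pc$x[!ref, seq_len(kmax), drop = FALSE], 2L, var)
    vn <- apply(pc$x[ref, seq_len(kmax), drop = FALSE], 2L, var)
    pass <- if (component_rule == "normal_total")
      vt > (1 + excess_fraction) * sum(vn)
    else
      vt > (1 + excess_fraction) * vn
    if (component_rule == "count") {
      keep <- sort(union(1L, which(pass)))
    } else {
      k <- if (all(pass)) kmax else which(!pass)[1L] - 1L
      keep <- seq_len(max(k, 1L))
    }
  } else {
    cum <- cumsum(pc$sdev[seq_len(kmax)]^2) / sum(pc$sdev^2)
    k <- which(cum >= fallback_variance)[1L]
    if (is.na(k)) k <- kmax
    k <- max(k, 1L)
    keep <- seq_len(k)
  }
  structure(
    list(process = name,
         scores = pc$x[, keep, drop = FALSE],
         loadings = pc$rotation[, keep, drop = FALSE],
         center = pc$center,
         k = length(keep),
         component_variances_tumor = vt[keep],
         component_variances_normal = vn[keep],
         is_reference = ref,
         genes_used = present),
    class = "mapping_space")
}

#' @export
print.mapping_space <- function(x, ...) {
  cat(sprintf("mapping space '%s': %d samples x k=%d components (%d genes)\n",
              x$process, nrow(x$scores), x$k, length(x$genes_used)))
  invisible(x)
}
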