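## Feature matrix coercion: accepts a bps object (processes x samples) or a
## plain samples x features matrix, returns samples x features.
as_feature_matrix <- function(features) {
  if (inherits(features, "bps")) return(t(features$values))
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  m
}

#' L1-penalized Cox proportional hazards fit
#'
#' Maximizes the lasso-penalized Cox partial likelihood over the feature
#' matrix (processes as predictors), selecting the penalty by internal
#' K-fold cross-validation with a deterministic fold assignment
#' (`penalty_selection = "cv"`, the default) or using a fixed `lambda`.
#' The cross-validation score is Harrell's concordance by default, matching
#' the discrimination objective the prognostic index is evaluated on
#' downstream; partial-likelihood deviance is available via `type_measure`
#' (it is noticeably more conservative -- with weak signals it often prefers
#' the empty model).
#'
#' @param features a `bps` object or samples x features numeric matrix.
#' @param time positive follow-up times, aligned with the samples.
#' @param status event indicators (1 = event, 0 = censored).
#' @param penalty_selection `"cv"` or `"fixed"`.
#' @param lambda penalty value when `penalty_selection = "fixed"`.
#' @param nfolds folds for the internal cross-validation (default 5).
#' @param type_measure cross-validation loss: `"C"` (Harrell's concordance,
#'   default) or `"deviance"`.
#' @return An object of class `cox_lasso`: list with `beta` (named
#'   coefficient vector), `selected` (features with nonzero beta), `lambda`,
#'   `penalty_selection` and the underlying glmnet fit.
#' @export
fit_cox_lasso <- function(features, time, status,
                          penalty_selection = c("cv", "fixed"),
                          lambda = NULL, nfolds = 5L,
                          type_measure = c("C", "deviance")) {
  penalty_selection <- match.arg(penalty_selection)
  type_measure <- match.arg(type_measure)
  x <- as_feature_matrix(features)
  if (any(!is.finite(x))) abort_argument("features must be finite")
  if (length(time) != nrow(x) || length(status) != nrow(x))
    abort_argument("`time`/`status` must align with the feature rows")
  if (sum(status == 1) < 2L) abort_argument("need >= 2 events to fit a Cox model")
  y <- survival::Surv(time, status)
  ## glmnet needs >= 2 columns; pad single-feature input with a null column
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, `.null.` = 0)
  if (penalty_selection == "cv") {
    foldid <- rep_len(seq_len(nfolds), nrow(x))  # deterministic assignment
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid,
                            type.measure = type_measure)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    if (is.null(lambda)) abort_argument("`lambda` required for fixed penalty")
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1)
  }
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda))
  names(beta) <- rownames(glmnet::coef.glmnet(fit, s = lambda))
  if (padded) beta <- beta[names(beta) != ".null."]
  structure(list(beta = beta, selected = names(beta)[beta != 0],
                 lambda = lambda, penalty_selection = penalty_selection,
                 glmnet_fit = fit),
            class = "cox_lasso")
}

#' @export
print.cox_lasso <- function(x, ...) {
  cat(sprintf("L1-penalized Cox model: %d/%d feature(s) selected (lambda = %.4g)\n",
              length(x$selected), length(x$beta), x$lambda))
  if (length(x$selected)) {
    print(round(x$beta[x$selected], 4))
  }
  invisible(x)
}

#' @export
coef.cox_lasso <- function(object, ...) object$beta

#' Prognostic index PI = beta' X per sample
#'
#' The Cox linear predictor, used as a per-sample survival risk score.
#'
#' @param model a `cox_lasso` fit.
#' @param features a `bps` object or samples x features matrix whose columns
#'   cover the model's features.
#' @return Named numeric vector of prognostic indices.
#' @export
prognostic_index <- function(model, features) {
  x <- as_feature_matrix(features)
  miss <- setdiff(names(model$beta), colnames(x))
  if (length(miss))
    abort_argument(sprintf("feature(s) missing from input: %s",
                           paste(miss, collapse = ", ")))
  drop(x[, names(model$beta), drop = FALSE] %*% model$beta)
}

#' @export
predict.cox_lasso <- function(object, newdata, ...) {
  prognostic_index(object, newdata)
}

#' Risk cutoff matching the training event fraction
#'
#' The threshold is the (1 - d) quantile of the training prognostic indices,
#' with d the training event fraction, so the fraction of samples labeled
#' high-risk (`pi > cutoff`) matches the dead:alive ratio of the training
#' data within 1/n (linear-interpolation quantile).
#'
#' @param pi_train training prognostic indices.
#' @param status_train training event indicators (0/1).
#' @return The cutoff value.
#' @export
pi_cutoff <- function(pi_train, status_train) {
  if (length(pi_train) != length(status_train))
    abort_argument("`pi_train` and `status_train` lengths differ")
  d <- mean(status_train == 1)
  if (d <= 0 || d >= 1)
    abort_argument("need at least one event and one non-event")
  cut <- stats::quantile(pi_train, probs = 1 - d, names = FALSE, type = 7)
  if (diff(range(pi_train)) <= 0)
    warning("all prognostic indices equal; every sample falls in one group")
  cut
}

#' Assign low/high risk groups by a prognostic-index cutoff
#'
#' @param pi prognostic indices.
#' @param cutoff threshold from [pi_cutoff()].
#' @return Factor with levels `low`, `high` (`high` iff `pi > cutoff`).
#' @export
risk_groups <- function(pi, cutoff) {
  factor(ifelse(pi > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Two-sample log-rank test
#'
#' Plain log-rank by default; `weighted = TRUE` uses the Peto-Prentice
#' weighting (the "Wilcoxon log-rank" family), emphasizing early differences.
#'
#' @param time follow-up times.
#' @param status event indicators (0/1).
#' @param group two-level grouping (factor or coercible).
#' @param weighted use the Peto-Prentice weighted statistic?
#' @return List with `chisq`, `p_value` and the `survival::survdiff` fit.
#' @export
logrank_test <- function(time, status, group, weighted = FALSE) {
  group <- factor(group)
  tab <- table(group)
  if (length(tab[tab > 0]) < 2L)
    abort_argument("log-rank test needs two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, status) ~ group,
                           rho = if (weighted) 1 else 0)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = unname(p), fit = sd)
}

#' Rank-based ROC AUC of a risk score against binary status
#'
#' The Wilcoxon/Mann-Whitney statistic with midranks for ties: the
#' probability that a random event sample scores above a random non-event
#' sample.
#'
#' @param pi risk scores.
#' @param status binary outcomes (0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pi, status) {
  status <- as.integer(status)
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 == 0L || n0 == 0L)
    abort_argument("both outcome classes must be present")
  r <- rank(pi)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Leave-one-out cross-validated survival evaluation
#'
#' For each fold the model is refitted on the remaining samples, the held-out
#' sample's prognostic index is computed with the training coefficients, and
#' its risk label is assigned against the training-derived cutoff. All
#' held-out indices are pooled for a single AUC, and the pooled risk groups
#' are compared by a log-rank test.
#'
#' @param features a `bps` object or samples x features matrix.
#' @param time follow-up times.
#' @param status event indicators (0/1).
#' @param penalty_selection passed to [fit_cox_lasso()].
#' @param nfolds internal lambda-CV folds per training fit.
#' @param lambda fixed penalty (with `penalty_selection = "fixed"`).
#' @param type_measure cross-validation loss, see [fit_cox_lasso()].
#' @param weighted_logrank use the weighted log-rank variant?
#' @return List with `auc`, `logrank_p` (`NA` when only one pooled group
#'   arises), and `per_sample` (one row per sample: pi, group, time, status).
#' @export
loocv_evaluate <- function(features, time, status,
                           penalty_selection = c("cv", "fixed"),
                           nfolds = 5L, lambda = NULL,
                           type_measure = c("C", "deviance"),
                           weighted_logrank = FALSE) {
  penalty_selection <- match.arg(penalty_selection)
  type_measure <- match.arg(type_measure)
  x <- as_feature_matrix(features)
  n <- nrow(x)
  if (n < 10L) abort_argument("LOOCV needs at least 10 samples")
  pi_out <- rep(NA_real_, n)
  grp_out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (sum(status[-i] == 1) < 2L) {
      warning(sprintf("fold %d skipped: no events in training data", i))
      next
    }
    fit <- fit_cox_lasso(x[-i, , drop = FALSE], time[-i], status[-i],
                         penalty_selection = penalty_selection,
                         lambda = lambda, nfolds = nfolds,
                         type_measure = type_measure)
    pi_tr <- prognostic_index(fit, x[-i, , drop = FALSE])
    cut <- tryCatch(suppressWarnings(pi_cutoff(pi_tr, status[-i])),
                    error = function(e) -Inf)  # all-event training folds
    pi_out[i] <- prognostic_index(fit, x[i, , drop = FALSE])
    grp_out[i] <- as.character(risk_groups(pi_out[i], cut))
  }
  ok <- !is.na(pi_out)
  auc <- roc_auc(pi_out[ok], status[ok])
  grp <- factor(grp_out[ok], levels = c("low", "high"))
  logrank_p <- if (nlevels(droplevels(grp)) == 2L)
    logrank_test(time[ok], status[ok], grp, weighted = weighted_logrank)$p_value
  else NA_real_
  list(auc = auc, logrank_p = logrank_p,
       per_sample = data.frame(sample = rownames(x) %||% seq_len(n),
                               pi = pi_out, group = grp_out,
                               time = time, status = status,
                               stringsAsFactors = FALSE))
}

#' Cluster the score matrix and test association with clinical factors
#'
#' Agglomerative hierarchical clustering of the samples (Euclidean distance,
#' average linkage by default) cut into two groups, followed by a chi-square
#' test of the group labels against each categorical clinical factor. When a
#' table has an expected cell count of zero the p-value is computed by Monte
#' Carlo simulation instead (noted in the output).
#'
#' @param features a `bps` object or samples x features matrix.
#' @param clinical_factors data.frame of categorical covariates, one row per
#'   sample.
#' @param linkage hclust linkage (default `"average"`).
#' @param k number of clusters (default 2).
#' @param simulate_B Monte Carlo replicates for the fallback p-value.
#' @return data.frame with one row per factor: `factor`, `p_value`, `method`
#'   (`chisq`, `simulated`, or `error: ...` for degenerate cases), plus the
#'   cluster labels as attribute `clusters`.
#' @export
cluster_association <- function(features, clinical_factors,
                                linkage = "average", k = 2L,
                                simulate_B = 2000L) {
  x <- as_feature_matrix(features)
  if (nrow(x) < 2L) abort_argument("need >= 2 samples to cluster")
  hc <- hclust(dist(x), method = linkage)
  cl <- cutree(hc, k = k)
  out <- lapply(names(clinical_factors), function(v) {
    f <- clinical_factors[[v]]
    if (!is.factor(f)) f <- factor(f)
    if (length(unique(cl)) < 2L)
      return(data.frame(factor = v, p_value = NA_real_,
                        method = "error: single cluster",
                        stringsAsFactors = FALSE))
    tab <- table(cluster = cl, factor = f)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      p <- with_seed(271828L,
                     suppressWarnings(chisq.test(tab, simulate.p.value = TRUE,
                                                 B = simulate_B))$p.value)
      method <- "simulated"
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
      method <- "chisq"
    }
    data.frame(factor = v, p_value = p, method = method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "clusters") <- cl
  res
}
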