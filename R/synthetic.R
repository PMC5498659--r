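#' Simulate a cohort with known per-process latent progression
#'
#' Generates the data structure the scoring method assumes: for every
#' process, tumor samples are spread along a latent 1-D progression
#' u ~ Uniform(0, 1) and each of the process's genes responds as a smooth
#' function of u plus Gaussian noise; normal (reference) samples sit at u = 0
#' with the same noise. Survival follows an exponential model whose
#' log-hazard is `hazard_coef` times the mean latent value of the driver
#' processes; censoring is administrative by default (a fixed follow-up
#' window calibrated so the expected censored fraction equals `censor_rate`),
#' with random-thinning and exponential-censor-time alternatives.
#'
#' Gene response shapes:
#' \describe{
#'   \item{`line`}{a_g + b_g u, slopes b_g ~ N(1, 0.5^2) (predominantly
#'     coherent co-regulation, so the progression direction is identifiable
#'     without a reference anchor).}
#'   \item{`arc`}{a_g cos(pi u) + b_g sin(pi u), a_g, b_g ~ N(0, 1): a
#'     genuinely curved 1-D manifold that a linear principal component cannot
#'     parameterize.}
#'   \item{`s-curve`}{a_g + b_g / (1 + exp(-10(u - 1/2))), a sigmoidal
#'     switch.}
#' }
#'
#' @param n_tumor number of tumor samples (>= 10).
#' @param n_normal number of normal/reference samples (>= 0).
#' @param n_processes number of gene sets.
#' @param genes_per_process genes per set (default 15, a small pathway).
#' @param n_drivers number of processes whose latent value drives hazard
#'   (0 gives a null cohort with hazard independent of all processes).
#' @param curve_shape `"line"`, `"arc"` or `"s-curve"`.
#' @param noise_sd Gaussian expression noise SD (default 0.05, i.e. 5% of
#'   the unit response amplitude).
#' @param hazard_coef log-hazard coefficient on the mean driver latent
#'   (default 2).
#' @param censor_rate expected censored fraction in `[0, 1]` (default 0.3).
#' @param censoring censoring mechanism: `"administrative"` (default),
#'   `"exponential"`, or `"thinning"` (completely random relabeling, which
#'   makes status independent of risk -- only useful for time-based tests).
#' @param base_hazard baseline hazard rate per time unit (default 0.1).
#' @param seed integer seed; the cohort is fully reproducible from it and the
#'   caller's RNG state is left untouched.
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (an [expression_matrix], tumor + normal columns), `genesets`
#'   (a [gene_sets] collection), `latent` (processes x tumor-samples matrix
#'   of true u), `driver_processes`, `clinical` (data.frame sample/time/
#'   status over tumor samples), `params`.
#' @examples
#' coh <- simulate_cohort(n_tumor = 40, n_normal = 8, n_processes = 2,
#'                        seed = 42)
#' coh
#' @export
simulate_cohort <- function(n_tumor = 200L, n_normal = 20L,
                            n_processes = 20L, genes_per_process = 15L,
                            n_drivers = 3L,
                            curve_shape = c("line", "arc", "s-curve"),
                            noise_sd = 0.05, hazard_coef = 2,
                            censor_rate = 0.3,
                            censoring = c("administrative", "exponential",
                                          "thinning"),
                            base_hazard = 0.1, seed = 1L) {
  curve_shape <- match.arg(curve_shape)
  censoring <- match.arg(censoring)
  if (n_tumor < 10L) abort_argument("`n_tumor` must be >= 10")
  if (n_normal < 0L) abort_argument("`n_normal` must be >= 0")
  if (n_processes < 1L || genes_per_process < 1L)
    abort_argument("dimensions must be positive")
  if (n_drivers < 0L || n_drivers > n_processes)
    abort_argument("`n_drivers` must be between 0 and `n_processes`")
  if (noise_sd < 0) abort_argument("`noise_sd` must be >= 0")
  if (censor_rate < 0 || censor_rate > 1)
    abort_argument("`censor_rate` must be in [0, 1]")

  with_seed(seed, {
    tumor_ids <- sprintf("T%03d", seq_len(n_tumor))
    normal_ids <- if (n_normal > 0L) sprintf("N%03d", seq_len(n_normal)) else character()
    proc_ids <- sprintf("PROC_%02d", seq_len(n_processes))

    latent <- matrix(runif(n_processes * n_tumor), n_processes, n_tumor,
                     dimnames = list(proc_ids, tumor_ids))
    response <- switch(curve_shape,
      "line" = function(a, b, u) a + b * u,
      "arc" = function(a, b, u) a * cos(pi * u) + b * sin(pi * u),
      "s-curve" = function(a, b, u) a + b / (1 + exp(-10 * (u - 0.5))))
    coef_a <- function(g) rnorm(g, 0, 1)
    coef_b <- function(g) {
      if (curve_shape == "arc") rnorm(g, 0, 1) else rnorm(g, 1, 0.5)
    }

    blocks <- vector("list", n_processes)
    sets <- vector("list", n_processes)
    for (p in seq_len(n_processes)) {
      gid <- sprintf("%s_G%03d", proc_ids[p], seq_len(genes_per_process))
      a <- coef_a(genes_per_process)
      b <- coef_b(genes_per_process)
      u_all <- c(latent[p, ], rep(0, n_normal))
      mu <- outer(seq_len(genes_per_process), seq_along(u_all),
                  function(g, s) response(a[g], b[g], u_all[s]))
      noise <- matrix(rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))
      blk <- mu + noise
      dimnames(blk) <- list(gid, c(tumor_ids, normal_ids))
      blocks[[p]] <- blk
      sets[[p]] <- gid
    }
    values <- do.call(rbind, blocks)

    drivers <- if (n_drivers > 0L) sort(sample(proc_ids, n_drivers)) else character()
    risk <- if (n_drivers > 0L)
      colMeans(latent[drivers, , drop = FALSE]) else rep(0, n_tumor)
    lam <- base_hazard * exp(hazard_coef * risk)
    t_event <- rexp(n_tumor, rate = lam)
    cens <- censor_times(lam, censor_rate, censoring, n_tumor)
    time <- pmin(t_event, cens$times)
    status <- as.integer(t_event <= cens$times)
    if (censoring == "thinning") {
      status <- cens$status
      time <- ifelse(status == 1L, t_event, runif(n_tumor, 0, t_event))
    }
    time <- pmax(time, .Machine$double.eps)

    structure(
      list(expression = expression_matrix(values, reference = normal_ids),
           genesets = gene_sets(setNames(sets, proc_ids),
                                description = sprintf("simulated %s process",
                                                      curve_shape)),
           latent = latent,
           driver_processes = drivers,
           clinical = data.frame(sample = tumor_ids, time = time,
                                 status = status, stringsAsFactors = FALSE),
           params = list(n_tumor = n_tumor, n_normal = n_normal,
                         n_processes = n_processes,
                         genes_per_process = genes_per_process,
                         n_drivers = n_drivers, curve_shape = curve_shape,
                         noise_sd = noise_sd, hazard_coef = hazard_coef,
                         censor_rate = censor_rate, censoring = censoring,
                         base_hazard = base_hazard, seed = seed)),
      class = "synthetic_cohort")
  })
}

## Censoring times for the chosen mechanism, calibrated against the realized
## hazard rates so the expected censored fraction equals censor_rate.
censor_times <- function(lam, censor_rate, censoring, n) {
  if (censor_rate <= 0)
    return(list(times = rep(Inf, n), status = rep(1L, n)))
  if (censor_rate >= 1)
    return(list(times = rep(0, n), status = rep(0L, n)))
  switch(censoring,
    "administrative" = {
      ## P(censored | lam) = exp(-lam * tau); solve mean over samples
      tau <- uniroot(function(tau) mean(exp(-lam * tau)) - censor_rate,
                     lower = 1e-8 / mean(lam), upper = 1e8 / mean(lam),
                     tol = 1e-10)$root
      list(times = rep(tau, n), status = NULL)
    },
    "exponential" = {
      ## P(censored | lam) = lc / (lam + lc)
      lc <- uniroot(function(lc) mean(lc / (lam + lc)) - censor_rate,
                    lower = 1e-10 * mean(lam), upper = 1e10 * mean(lam),
                    tol = 1e-12)$root
      list(times = rexp(n, rate = lc), status = NULL)
    },
    "thinning" = {
      list(times = rep(Inf, n),
           status = as.integer(runif(n) >= censor_rate))
    })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic cohort (seed %d): %d tumor + %d normal samples, %d process(es) x %d genes, shape '%s'\n",
              p$seed, p$n_tumor, p$n_normal, p$n_processes,
              p$genes_per_process, p$curve_shape))
  if (length(x$driver_processes))
    cat(sprintf("  hazard drivers: %s (coef %.3g)\n",
                paste(x$driver_processes, collapse = ", "), p$hazard_coef))
  cat(sprintf("  events: %d/%d\n", sum(x$clinical$status), p$n_tumor))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv`, `genesets.gmt`, `clinical.tsv` (columns sample,
#' time, status) and `truth.tsv` (sample, process, latent; for tests only).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gmt(cohort$genesets, file.path(dir, "genesets.gmt"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(
    sample = rep(colnames(cohort$latent), each = nrow(cohort$latent)),
    process = rep(rownames(cohort$latent), ncol(cohort$latent)),
    latent = as.vector(cohort$latent))
  write.table(truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
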