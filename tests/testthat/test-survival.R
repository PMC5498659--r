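# Simulated survival helper: exponential times with a known linear risk.
sim_surv <- function(n, beta_x, seed, censor = 0.3) {
  set.seed(seed)
  x <- matrix(runif(n * length(beta_x)), n,
              dimnames = list(NULL, paste0("f", seq_along(beta_x))))
  lam <- 0.1 * exp(drop(x %*% beta_x))
  tt <- rexp(n, lam)
  tau <- uniroot(function(tau) mean(exp(-lam * tau)) - censor,
                 c(1e-6, 1e6))$root
  list(x = x, time = pmin(tt, tau), status = as.integer(tt <= tau))
}

test_that("the penalized Cox fit recovers signs and shrinks to zero", {
  sv <- sim_surv(300, c(2, 0), seed = 1)
  fit <- fit_cox_lasso(sv$x, sv$time, sv$status)
  expect_gt(fit$beta["f1"], 0)
  ## single informative feature keeps the right sign
  one <- fit_cox_lasso(sv$x[, 1, drop = FALSE], sv$time, sv$status)
  expect_gt(one$beta["f1"], 0)
  expect_length(one$beta, 1)
  ## an enormous penalty removes every coefficient
  none <- fit_cox_lasso(sv$x, sv$time, sv$status,
                        penalty_selection = "fixed", lambda = 1e6)
  expect_true(all(none$beta == 0))
  expect_length(none$selected, 0)
})

test_that("prognostic indices are the Cox linear predictor", {
  fake <- structure(list(beta = c(a = 1, b = -2)), class = "cox_lasso")
  x <- matrix(c(0.5, 0.25), 1, dimnames = list("s", c("a", "b")))
  expect_equal(unname(prognostic_index(fake, x)), 0)
  zero <- structure(list(beta = c(a = 0, b = 0)), class = "cox_lasso")
  expect_equal(unname(prognostic_index(zero, x)), 0)
  e1 <- structure(list(beta = c(a = 1, b = 0)), class = "cox_lasso")
  expect_equal(unname(prognostic_index(e1, x)), 0.5)
  expect_error(prognostic_index(fake, x[, 1, drop = FALSE]), "missing",
               class = "lpcscore_argument_error")
})

test_that("the cutoff reproduces the training event fraction", {
  cut <- pi_cutoff(c(1, 2, 3, 4), c(0, 0, 0, 1))
  expect_gt(cut, 3); expect_lt(cut, 4)
  expect_equal(sum(c(1, 2, 3, 4) > cut), 1)
  ## d = 0.5 with distinct values is a median split
  expect_equal(pi_cutoff(1:10, rep(c(0, 1), 5)), median(1:10))
  expect_warning(pi_cutoff(rep(2, 6), c(1, 0, 0, 1, 0, 0)), "one group")
  expect_error(pi_cutoff(1:4, rep(1, 4)), class = "lpcscore_argument_error")
})

test_that("the high-risk fraction matches the event fraction within 1/n", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:200, 1)
    pi <- rnorm(n)                       # continuous: distinct a.s.
    status <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (sum(status) == 0 || sum(status) == n) next
    cut <- pi_cutoff(pi, status)
    expect_lte(abs(mean(pi > cut) - mean(status)), 1 / n + 1e-12)
  }
})

test_that("log-rank behaviour: null, separation, and label symmetry", {
  set.seed(2)
  time <- rexp(80); status <- rbinom(80, 1, 0.7)
  grp <- rep(c("a", "b"), 40)
  null_p <- logrank_test(time, status, grp)$p_value
  expect_gt(null_p, 0.01)
  swapped <- logrank_test(time, status, ifelse(grp == "a", "b", "a"))$p_value
  expect_equal(null_p, swapped, tolerance = 1e-12)

  ## hazard ratio 5 with 100 per arm separates decisively
  set.seed(3)
  t2 <- c(rexp(100, 1), rexp(100, 5))
  g2 <- rep(c("lo", "hi"), each = 100)
  expect_lt(logrank_test(t2, rep(1, 200), g2)$p_value, 0.01)
  ## the weighted variant is a valid p-value too
  expect_lt(logrank_test(t2, rep(1, 200), g2, weighted = TRUE)$p_value, 0.01)
  expect_error(logrank_test(t2, rep(1, 200), rep("one", 200)),
               class = "lpcscore_argument_error")
})

test_that("the AUC equals brute-force pairwise concordance", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(-c(1, 2, 3, 4), c(0, 0, 1, 1)), 0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:50, 1)
    pi <- rnorm(n); pi[sample(n, 3)] <- pi[1]   # inject ties
    status <- rbinom(n, 1, 0.5)
    if (length(unique(status)) < 2) next
    got <- roc_auc(pi, status)
    pos <- pi[status == 1]; neg <- pi[status == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
    expect_equal(roc_auc(-pi, status), 1 - got, tolerance = 1e-12)
  }
  ## independent score: AUC near 1/2
  set.seed(11)
  expect_lt(abs(roc_auc(rnorm(2000), rbinom(2000, 1, 0.5)) - 0.5), 0.05)
})

test_that("PI is affine-equivariant through the evaluation chain", {
  sv <- sim_surv(150, c(1.5, -1), seed = 4)
  fit <- fit_cox_lasso(sv$x, sv$time, sv$status)
  pi0 <- prognostic_index(fit, sv$x)
  shift <- pi0 + 3.14
  expect_equal(roc_auc(shift, sv$status), roc_auc(pi0, sv$status))
  cut0 <- pi_cutoff(pi0, sv$status)
  cut1 <- pi_cutoff(shift, sv$status)
  expect_identical(risk_groups(shift, cut1), risk_groups(pi0, cut0))
})

test_that("LOOCV books every sample and stays null-calibrated", {
  sv <- sim_surv(40, c(0, 0), seed = 5)
  res <- loocv_evaluate(sv$x, sv$time, sv$status,
                        penalty_selection = "fixed", lambda = 0.05)
  expect_equal(nrow(res$per_sample), 40)
  expect_true(all(!is.na(res$per_sample$pi)))
  expect_lt(abs(res$auc - 0.5), 0.25)   # small-n null
})

test_that("a transferred cutoff dichotomizes an independent cohort", {
  train <- sim_surv(200, c(2), seed = 6)
  test <- sim_surv(150, c(2), seed = 7)
  fit <- fit_cox_lasso(train$x, train$time, train$status)
  cut <- pi_cutoff(prognostic_index(fit, train$x), train$status)
  grp <- risk_groups(prognostic_index(fit, test$x), cut)
  expect_equal(levels(grp), c("low", "high"))
  expect_true(all(table(grp) > 0))
  p <- logrank_test(test$time, test$status, grp)$p_value
  expect_lt(p, 0.05)
})

test_that("cluster association separates signal from null factors", {
  ## factor identical to the cluster split: p below 1e-6 at n = 100
  set.seed(8)
  grp <- rep(c(0, 3), each = 50)
  feats <- cbind(grp + rnorm(100, 0, 0.2), rnorm(100, 0, 0.2))
  res <- cluster_association(feats, data.frame(lab = grp))
  expect_lt(res$p_value[1], 1e-6)
  expect_equal(res$method[1], "chisq")

  ## independent factor: p-values spread over (0, 1)
  ps <- sapply(1:50, function(s) {
    set.seed(100 + s)
    f <- matrix(rnorm(200 * 4), 200, 4)
    cluster_association(f, data.frame(x = rbinom(200, 1, 0.5)))$p_value
  })
  expect_gt(median(ps, na.rm = TRUE), 0.2)
  expect_lt(median(ps, na.rm = TRUE), 0.8)
})

test_that("degenerate clusterings are reported per factor", {
  ## one far outlier: single-link style degenerate split still yields 2
  ## groups under average linkage, so force k with identical points instead
  x <- matrix(0, 10, 2)
  x[1, ] <- c(100, 100)
  res <- cluster_association(x, data.frame(f = rep(c("a", "b"), 5)))
  expect_true(all(c("factor", "p_value", "method") %in% names(res)))
  ## expected-zero cells switch to the simulated p-value
  y <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) + rnorm(20, 0, 0.01)
  res2 <- cluster_association(y, data.frame(f = factor(rep("only", 10),
                                                       levels = c("only", "never"))))
  expect_equal(res2$method, "simulated")
})
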