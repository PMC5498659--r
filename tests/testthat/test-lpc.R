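test_that("bandwidths follow the 10%-of-range rule per dimension", {
  x <- cbind(seq(0, 10, length.out = 20))
  expect_equal(lpc_bandwidth(x), 1.0)
  two <- cbind(seq(0, 1, length.out = 11), seq(-5, 5, length.out = 11))
  expect_equal(lpc_bandwidth(two), c(0.1, 1.0))
  ## homogeneity: scaling the data scales the bandwidth
  expect_equal(lpc_bandwidth(3.7 * two), 3.7 * c(0.1, 1.0))
  ## degenerate dimension falls back to pooled SD with a warning
  degen <- cbind(seq(0, 1, length.out = 11), rep(2, 11))
  expect_warning(h <- lpc_bandwidth(degen), "degenerate")
  expect_gt(h[2], 0)
})

test_that("kernel weights normalize, respect symmetry, and match the Gaussian", {
  expect_equal(kernel_weights(c(0, 0), matrix(1:2, 1), c(1, 1)), 1.0)
  sym <- matrix(c(-1, 1), 2, 1)
  expect_equal(kernel_weights(0, sym, 1), c(0.5, 0.5))
  ## direct Gaussian evaluation: x = 0, points {0, 1}, h = 1
  w <- kernel_weights(0, matrix(c(0, 1), 2, 1), 1)
  expect_equal(w, c(dnorm(0), dnorm(1)) / (dnorm(0) + dnorm(1)),
               tolerance = 1e-12)
  expect_equal(w, c(0.6224593, 0.3775407), tolerance = 1e-6)
})

test_that("kernel weights sum to one over random configurations", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:50, 1); p <- sample(1:5, 1)
    pts <- matrix(rnorm(n * p, sd = runif(1, 0.1, 10)), n, p)
    x <- rnorm(p, sd = 2)
    h <- runif(p, 0.05, 2)
    expect_lt(abs(sum(kernel_weights(x, pts, h)) - 1), 1e-12)
  }
})

test_that("local centers of mass are convex combinations of the data", {
  expect_equal(local_center_of_mass(0, matrix(c(-1, 1), 2, 1), 1), 0)
  expect_equal(local_center_of_mass(0, matrix(c(0, 1), 2, 1), 1),
               0.3775407, tolerance = 1e-6)
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(rnorm(40), 20, 2)
    mu <- local_center_of_mass(rnorm(2), pts, c(0.5, 0.5))
    expect_true(in_hull_2d(mu, pts))
  }
})

test_that("the local first eigenvector matches an eigen oracle with sign rules", {
  ## four points placed so the kernel weights are exactly equal and the
  ## weighted covariance is exactly diag(2, 1)
  pts <- rbind(c(2, 0), c(-2, 0), c(0, sqrt(2)), c(0, -sqrt(2)))
  h <- c(2, sqrt(2))   # equal Mahalanobis radius for all four points
  w <- kernel_weights(c(0, 0), pts, h)
  expect_equal(w, rep(0.25, 4), tolerance = 1e-12)
  sigma <- crossprod(pts, pts * w)
  expect_equal(sigma, diag(c(2, 1)), ignore_attr = TRUE, tolerance = 1e-12)
  g <- local_first_eigenvector(c(0, 0), pts, h)
  expect_equal(g, c(1, 0), tolerance = 1e-10)
  ## sign continuity against a previous direction
  g2 <- local_first_eigenvector(c(0, 0), pts, h, prev_dir = c(-1, 0))
  expect_equal(g2, c(-1, 0), tolerance = 1e-10)
  ## collinear data: direction resolves to +e1 without prev_dir
  line <- cbind(seq(-1, 1, length.out = 9), 0)
  expect_equal(abs(local_first_eigenvector(c(0, 0), line, c(0.5, 0.5))),
               c(1, 0), tolerance = 1e-10)
})

test_that("LPC on noiseless collinear data recovers the segment", {
  dirv <- c(3, 4) / 5
  u <- seq(0, 10, length.out = 200)
  pts <- outer(u, dirv)
  path <- fit_lpc(pts, x0 = pts[1, ], h = lpc_bandwidth(pts))
  ## centers collinear with the segment
  res <- apply(path$centers, 1, function(p) abs(p[1] * dirv[2] - p[2] * dirv[1]))
  expect_lt(max(res), 1e-8)
  ## span at least 95% of the segment
  proj <- path$centers %*% dirv
  expect_gt(diff(range(proj)), 0.95 * 10)

  ## two-sided from the middle covers both halves
  both <- fit_lpc(pts, x0 = pts[100, ], h = lpc_bandwidth(pts),
                  two_sided = TRUE)
  pr <- both$centers %*% dirv
  expect_lt(min(pr), 2)
  expect_gt(max(pr), 8)
})

test_that("a fixed step bounds consecutive center spacing", {
  set.seed(3)
  u <- sort(runif(300, 0, 10))
  pts <- cbind(u, 0.2 * sin(u)) + matrix(rnorm(600, 0, 0.05), ncol = 2)
  h <- lpc_bandwidth(pts)
  t0 <- mean(h)
  path <- fit_lpc(pts, x0 = c(0, 0), h = h, step = t0)
  gaps <- sqrt(rowSums(diff(path$centers)^2))
  expect_lt(max(gaps), 2 * t0)
})

test_that("LPC centers track a noisy semicircle", {
  sc <- semicircle_points(n = 300, noise = 0.05, seed = 4, n_ref = 0)
  path <- fit_lpc(sc$x, x0 = c(1, 0), h = lpc_bandwidth(sc$x),
                  two_sided = TRUE)
  radii <- sqrt(rowSums(path$centers^2))
  expect_lt(mean(abs(radii - 1)), 0.1)
})

test_that("LPC paths are translation- and rotation-equivariant", {
  set.seed(5)
  u <- runif(250, 0, 2 * pi / 3)
  pts <- cbind(cos(u), sin(u)) + matrix(rnorm(500, 0, 0.04), ncol = 2)
  h <- c(0.15, 0.15)  # isotropic, so rotations commute with the kernel
  d0 <- c(0, 1)
  base <- fit_lpc(pts, x0 = c(1, 0), h = h, init_dir = d0)

  v <- c(3, -7)
  shifted <- fit_lpc(sweep(pts, 2, v, "+"), x0 = c(1, 0) + v, h = h,
                     init_dir = d0)
  expect_lt(max(abs(sweep(shifted$centers, 2, v) - base$centers)), 1e-8)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotated <- fit_lpc(pts %*% t(R), x0 = drop(R %*% c(1, 0)), h = h,
                     init_dir = drop(R %*% d0))
  expect_lt(max(abs(rotated$centers - base$centers %*% t(R))), 1e-8)
})

test_that("degenerate starting points raise an informative error", {
  one <- matrix(c(0, 0, 1e-3, 0), 2, 2, byrow = TRUE)
  expect_error(fit_lpc(one, x0 = c(100, 100), h = c(1e-4, 1e-4)),
               class = "lpcscore_degenerate")
})

test_that("starting points come from references or a density mode", {
  pts <- rbind(c(0, 0), c(2, 2), c(5, 1))
  expect_equal(choose_start(pts, reference = c(TRUE, TRUE, FALSE)), c(1, 1))
  expect_equal(choose_start(pts, reference = 1:3), colMeans(pts))
  ## single Gaussian blob: the mean-shift mode lands near the center
  set.seed(6)
  blob <- matrix(rnorm(800, mean = 3, sd = 1), ncol = 2)
  h <- lpc_bandwidth(blob)
  mode <- choose_start(blob, reference = NULL, h = h)
  expect_lt(sqrt(sum((mode - c(3, 3))^2)), 0.5 * mean(h))
})

test_that("the linear-data oracle ties the LPC to the first principal component", {
  set.seed(7)
  u <- runif(300)
  dirv <- c(1, 2) / sqrt(5)
  pts <- outer(u, dirv)
  fit <- lpc(pts, start = outer(min(u), dirv)[1, ])
  ## centers lie on the PC1 line through the data
  pc <- prcomp(pts)
  res <- apply(sweep(fit$centers, 2, pc$center), 1, function(p)
    sqrt(sum((p - sum(p * pc$rotation[, 1]) * pc$rotation[, 1])^2)))
  expect_lt(max(res), 1e-6)
  ## projection indices rank-match the PC1 scores
  expect_equal(abs(cor(rank(fitted(fit)), rank(pc$x[, 1]))), 1)
})

test_that("the lpc model object supports the standard methods", {
  sc <- semicircle_points(n = 150, noise = 0.05, seed = 8, n_ref = 10)
  fit <- lpc(sc$x, reference = sc$is_ref)
  expect_s3_class(fit, "lpc")
  expect_output(print(fit), "Local principal curve")
  expect_output(print(summary(fit)), "projection index range")
  expect_length(fitted(fit), nrow(sc$x))
  expect_true(all(residuals(fit) >= 0))
  pr <- predict(fit, sc$x[1:5, ])
  expect_equal(pr$t, fit$projections$t[1:5], tolerance = 1e-10)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})
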