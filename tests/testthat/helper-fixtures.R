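# Shared fixture builders and independent oracles, all generated in code.

# Noisy semicircle of radius 1 plus an optional cluster of reference points
# at angle 0 (the "normal" end).
semicircle_points <- function(n = 300, noise = 0.05, seed = 1, n_ref = 20) {
  withr_seed(seed)
  theta <- runif(n, 0, pi)
  pts <- cbind(cos(theta), sin(theta)) +
    matrix(rnorm(2 * n, 0, noise), ncol = 2)
  ref <- if (n_ref > 0)
    cbind(1 + rnorm(n_ref, 0, noise), rnorm(n_ref, 0, noise))
  else NULL
  list(x = rbind(pts, ref), theta = theta,
       is_ref = c(rep(FALSE, n), rep(TRUE, n_ref)))
}

# local seed helper (tests only)
withr_seed <- function(seed) set.seed(seed)

# 2-D point-in-convex-hull test via half-plane checks on the hull polygon.
in_hull_2d <- function(pt, cloud, tol = 1e-9) {
  hull <- cloud[chull(cloud), , drop = FALSE]
  k <- nrow(hull)
  signs <- vapply(seq_len(k), function(i) {
    a <- hull[i, ]; b <- hull[if (i == k) 1L else i + 1L, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, 0)
  all(signs <= tol) || all(signs >= -tol)
}

# Brute-force projection oracle: dense grid over the curve support plus the
# two tangent-extension rays, independent of the optimizer under test.
brute_force_project <- function(curve, x, n_grid = 1e5, pad = NULL) {
  s_lo <- curve$knots_s[1]
  s_hi <- curve$knots_s[length(curve$knots_s)]
  pad <- pad %||% (s_hi - s_lo)
  s_dense <- seq(s_lo, s_hi, length.out = n_grid)
  pts <- curve_point(curve, s_dense)
  d2 <- colSums((t(pts) - x)^2)
  i <- which.min(d2)
  t_best <- stats::approx(curve$s_grid, curve$t_grid, xout = s_dense[i])$y
  d_best <- sqrt(d2[i])
  ## ray candidates in closed form (projection onto a half-line)
  q_lo <- min(sum((x - curve$end_points$lower) * curve$end_tangents$lower), 0)
  d_lo <- sqrt(sum((x - (curve$end_points$lower +
                           q_lo * curve$end_tangents$lower))^2))
  if (q_lo < 0 && d_lo < d_best) {
    d_best <- d_lo
    t_best <- curve$t_grid[1] + q_lo
  }
  q_hi <- max(sum((x - curve$end_points$upper) * curve$end_tangents$upper), 0)
  d_hi <- sqrt(sum((x - (curve$end_points$upper +
                           q_hi * curve$end_tangents$upper))^2))
  if (q_hi > 0 && d_hi < d_best) {
    d_best <- d_hi
    t_best <- curve$t_grid[length(curve$t_grid)] + q_hi
  }
  list(t = t_best - curve$origin_t, distance = d_best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny expression fixture: 4 genes x 5 samples, 2 reference samples.
tiny_expr <- function() {
  v <- matrix(c(1, 3, 6, 2, 4,
                2, 2, 5, 1, 3,
                0, 4, 2, 8, 6,
                5, 5, 5, 5, 5),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expression_matrix(v, reference = c("s1", "s2"))
}
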