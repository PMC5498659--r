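#' Range-based kernel bandwidth
#'
#' One bandwidth per dimension, set to a fixed fraction (default 10%) of that
#' dimension's data range. The implied bandwidth matrix is
#' H = diag(h_1^2, ..., h_p^2). A dimension with zero range gets
#' `fraction * pooled SD` instead, with a warning.
#'
#' @param x numeric matrix, points in rows.
#' @param fraction fraction of the per-dimension range (default 0.10).
#' @return Numeric vector of per-dimension bandwidths `h`.
#' @export
lpc_bandwidth <- function(x, fraction = 0.10) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort_argument("need >= 2 points for a bandwidth")
  if (!is_scalar_number(fraction) || fraction <= 0)
    abort_argument("`fraction` must be a positive number")
  rng <- apply(x, 2L, range)
  h <- fraction * (rng[2L, ] - rng[1L, ])
  zero <- h <= 0
  if (any(zero)) {
    pooled <- sqrt(mean(apply(x, 2L, var)))
    if (pooled <= 0) abort_argument("all dimensions are degenerate")
    warning(sprintf("%d degenerate dimension(s); bandwidth set to fraction * pooled SD",
                    sum(zero)))
    h[zero] <- fraction * pooled
  }
  unname(h)
}

## Unnormalized Gaussian kernel mass K_H(X_i - x) for every data point.
## K_H(u) = |H|^{-1/2} K(H^{-1/2} u) with K the standard multivariate normal
## density and H = diag(h^2).
kernel_mass <- function(x, scores, h) {
  u <- sweep(scores, 2L, x, "-")
  u <- sweep(u, 2L, h, "/")
  exp(-0.5 * rowSums(u * u)) / (prod(h) * (2 * pi)^(ncol(scores) / 2))
}

#' Normalized Gaussian kernel weights around a point
#'
#' w_i = K_H(X_i - x) / sum_j K_H(X_j - x) with a diagonal-bandwidth Gaussian
#' kernel; the weights sum to one. If every kernel value underflows to zero
#' the neighborhood is empty and a degeneracy condition is signalled (used by
#' the traversal's boundary detection).
#'
#' @param x evaluation point (length-p numeric).
#' @param scores numeric matrix of data points (rows).
#' @param h per-dimension bandwidths, e.g. from [lpc_bandwidth()].
#' @return Numeric weight vector of length `nrow(scores)`.
#' @export
kernel_weights <- function(x, scores, h) {
  m <- kernel_mass(x, as.matrix(scores), h)
  s <- sum(m)
  if (s <= 0 || !is.finite(s))
    signal_degenerate("empty kernel neighborhood")
  m / s
}

#' Kernel-weighted local center of mass
#'
#' mu^x = sum_i w_i X_i with weights from [kernel_weights()]; always lies in
#' the convex hull of the data.
#'
#' @inheritParams kernel_weights
#' @return Length-p numeric vector.
#' @export
local_center_of_mass <- function(x, scores, h) {
  scores <- as.matrix(scores)
  w <- kernel_weights(x, scores, h)
  colSums(w * scores)
}

#' First eigenvector of the local weighted covariance
#'
#' The local covariance at `x` is Sigma^x with entries
#' sigma_jk = sum_i w_i (X_ij - mu_j)(X_ik - mu_k); its top unit eigenvector
#' gives the local tangent direction. The sign is made deterministic: aligned
#' with `prev_dir` when given (dot product >= 0), otherwise the first nonzero
#' coordinate is made positive.
#'
#' @inheritParams kernel_weights
#' @param mu local center of mass; computed from `x` when `NULL`.
#' @param prev_dir previous step's direction, for sign continuity; or `NULL`.
#' @return Unit-norm numeric vector of length p.
#' @export
local_first_eigenvector <- function(x, scores, h, mu = NULL, prev_dir = NULL) {
  scores <- as.matrix(scores)
  w <- kernel_weights(x, scores, h)
  if (is.null(mu)) mu <- colSums(w * scores)
  xc <- sweep(scores, 2L, mu, "-")
  sigma <- crossprod(xc, xc * w)
  if (max(abs(sigma)) < .Machine$double.xmin)
    signal_degenerate("zero local covariance")
  e <- eigen(sigma, symmetric = TRUE)
  if (e$values[1L] <= 0) signal_degenerate("degenerate local covariance")
  g <- e$vectors[, 1L]
  if (!is.null(prev_dir)) {
    if (sum(g * prev_dir) < 0) g <- -g
  } else {
    i <- which(abs(g) > 1e-12)[1L]
    if (!is.na(i) && g[i] < 0) g <- -g
  }
  g
}

## One directed traversal of the LPC iteration. Returns the recorded centers,
## the stop reason, and the direction taken at the first step (so the caller
## can launch the opposite traversal).
lpc_traverse <- function(scores, x0, h, step, tol, max_iter, angle_penalty,
                         boundary_frac, init_dir = NULL,
                         boundary_correction = TRUE, peak = 0) {
  p <- ncol(scores)
  centers <- matrix(NA_real_, max_iter, p)
  cur <- x0
  prev_dir <- init_dir
  first_dir <- NULL
  mu_prev <- NULL
  reason <- "max_iter"
  l <- 0L
  for (it in seq_len(max_iter)) {
    m <- kernel_mass(cur, scores, h)
    tot <- sum(m)
    if (tot <= 0 || !is.finite(tot) || (peak > 0 && tot < boundary_frac * peak)) {
      reason <- "boundary"
      break
    }
    peak <- max(peak, tot)
    ## boundary correction: as the kernel mass decays toward the edge of the
    ## cloud, shrink the bandwidth so the local center of mass can follow the
    ## data all the way to its extremes instead of stalling ~1 bandwidth short
    h_eff <- h
    if (boundary_correction && tot < peak) {
      shrink <- max(sqrt(tot / peak), 0.25)
      if (shrink < 1) {
        h_eff <- h * shrink
        m <- kernel_mass(cur, scores, h_eff)
        tot <- sum(m)
        if (tot <= 0 || !is.finite(tot)) {
          reason <- "boundary"
          break
        }
      }
    }
    w <- m / tot
    mu <- colSums(w * scores)
    ## loop detection: a center returning within half a bandwidth (kernel
    ## metric) of a center laid down > 5 steps earlier means the walker has
    ## U-turned at a boundary and is re-tracing the curve
    if (l > 5L) {
      old <- centers[seq_len(l - 5L), , drop = FALSE]
      d_h <- sqrt(rowSums(sweep(sweep(old, 2L, mu, "-"), 2L, h, "/")^2))
      if (min(d_h) < 0.5) {
        reason <- "loop"
        break
      }
    }
    l <- l + 1L
    centers[l, ] <- mu
    if (!is.null(mu_prev) && vec_norm(mu - mu_prev) < tol) {
      reason <- "converged"
      break
    }
    g <- tryCatch(
      local_first_eigenvector(cur, scores, h_eff, mu = mu, prev_dir = prev_dir),
      lpcscore_degenerate = function(e) NULL)
    if (is.null(g)) {
      reason <- "degenerate"
      break
    }
    if (is.null(first_dir)) first_dir <- g
    if (!is.null(prev_dir) && angle_penalty < 1)
      g <- unit(angle_penalty * g + (1 - angle_penalty) * prev_dir)
    ## NULL step: move one bandwidth in the kernel metric -- the step length
    ## is ||(g_j h_j)|| so it adapts to the travel direction (equals h in an
    ## isotropic space, the cited convention; a direction-independent step
    ## can trap the walker in anisotropic spaces)
    t0 <- step %||% vec_norm(g * h)
    cur <- mu + t0 * g
    prev_dir <- g
    mu_prev <- mu
  }
  list(centers = centers[seq_len(l), , drop = FALSE],
       reason = reason, first_dir = first_dir)
}

#' Fit the sequence of local centers of mass (raw LPC path)
#'
#' Alternates the three bottom-up steps -- kernel-weighted center of mass,
#' local first eigenvector, step of size `step` along it -- from the starting
#' point until the center of mass stops moving (difference below `tol`), the
#' boundary of the data cloud is reached (total kernel mass falls below
#' `boundary_frac` of its largest visited value), or `max_iter` iterations.
#' With `two_sided = TRUE` a second traversal is launched from `x0` in the
#' opposite initial direction and prepended in reverse. A traversal also
#' stops (`stop_reason = "loop"`) when its new center returns within half a
#' bandwidth of a much older center -- the signature of a U-turn at the data
#' boundary that would re-trace the curve.
#'
#' @param scores numeric matrix of points (rows) in the mapping space.
#' @param x0 starting point, e.g. from [choose_start()].
#' @param h per-dimension bandwidths; default [lpc_bandwidth()] of `scores`.
#' @param step step size t_0; `NULL` (default) moves one kernel bandwidth in
#'   the travel direction per iteration, i.e. t_0 = ||(gamma_j h_j)||, which
#'   reduces to `h` in an isotropic space.
#' @param tol convergence threshold on consecutive centers of mass; default
#'   `1e-3 * mean(h)`.
#' @param max_iter maximum iterations per direction (default 150; with
#'   bandwidth-length steps a traversal of 150 steps covers the data cloud
#'   many times over, so the cap only curtails boundary-skimming tails).
#' @param angle_penalty blending weight in `[0, 1]` applied to the new
#'   direction against the previous one (1 = pure sign-flip continuity, the
#'   default; smaller values damp oversteering).
#' @param boundary_frac kernel-mass fraction defining the data-cloud boundary
#'   (default 0.001; mass that far below the peak lies solidly outside the
#'   support, so the recorded centers reach the data extremes).
#' @param boundary_correction shrink the bandwidth in proportion to the
#'   square root of the kernel-mass decay near the data-cloud edge (floor at
#'   25% of `h`), so the recorded centers reach the data extremes instead of
#'   stopping about one bandwidth short (the classic LPC boundary bias)?
#'   Default TRUE.
#' @param two_sided grow the curve in both directions from `x0`?
#' @param init_dir optional unit vector forcing the initial direction of the
#'   forward traversal (useful for equivariance checks and reproducible
#'   orientations).
#' @return An object of class `lpc_path`: list with `centers` (L x p matrix),
#'   `start_point`, `step_size`, `stop_reason` (per direction), `h`.
#' @export
fit_lpc <- function(scores, x0, h = NULL, step = NULL, tol = NULL,
                    max_iter = NULL, angle_penalty = 1, boundary_frac = 0.001,
                    two_sided = FALSE, init_dir = NULL,
                    boundary_correction = TRUE) {
  scores <- as.matrix(scores)
  if (any(!is.finite(x0))) abort_argument("`x0` must be finite")
  h <- h %||% lpc_bandwidth(scores)
  if (!is.null(step) && step <= 0) abort_argument("`step` must be positive")
  tol <- tol %||% (1e-3 * mean(h))
  max_iter <- max_iter %||% 150L
  if (!is_scalar_number(angle_penalty) || angle_penalty < 0 || angle_penalty > 1)
    abort_argument("`angle_penalty` must be in [0, 1]")

  ## the cloud's density peak anchors the boundary criterion and the
  ## boundary bandwidth correction for both traversals
  peak <- max(vapply(seq_len(nrow(scores)),
                     function(i) sum(kernel_mass(scores[i, ], scores, h)), 0))
  fwd <- lpc_traverse(scores, x0, h, step, tol, max_iter, angle_penalty,
                      boundary_frac, init_dir = init_dir,
                      boundary_correction = boundary_correction, peak = peak)
  if (is.null(fwd$first_dir) || nrow(fwd$centers) == 0L)
    abort("no local structure at starting point", "lpcscore_degenerate")
  centers <- fwd$centers
  reasons <- c(forward = fwd$reason)
  if (two_sided) {
    bwd <- lpc_traverse(scores, x0, h, step, tol, max_iter, angle_penalty,
                        boundary_frac, init_dir = -fwd$first_dir,
                        boundary_correction = boundary_correction, peak = peak)
    reasons <- c(backward = bwd$reason, reasons)
    if (nrow(bwd$centers) > 1L) {
      back <- bwd$centers[rev(seq_len(nrow(bwd$centers))[-1L]), , drop = FALSE]
      centers <- rbind(back, centers)
    }
  }
  ## collapse consecutive duplicates so chord lengths are strictly increasing
  if (nrow(centers) > 1L) {
    d <- sqrt(rowSums((centers[-1L, , drop = FALSE] -
                         centers[-nrow(centers), , drop = FALSE])^2))
    centers <- centers[c(TRUE, d > 1e-12), , drop = FALSE]
  }
  if (nrow(centers) < 2L)
    abort("no local structure at starting point", "lpcscore_degenerate")
  structure(list(centers = centers, start_point = x0,
                 step_size = step %||% NA_real_,  # NA = adaptive (one kernel bandwidth)
                 stop_reason = reasons, h = h),
            class = "lpc_path")
}

#' Choose the curve's starting point
#'
#' With reference rows, the coordinate-wise mean of the reference points
#' (the "central point of reference samples" convention). Without, a mean-shift
#' iteration with the same Gaussian kernel and bandwidth, started from the
#' sample point of maximal kernel density, converging to a density mode.
#'
#' @param scores numeric matrix of points (rows).
#' @param reference logical/integer index of reference rows, or `NULL`.
#' @param h per-dimension bandwidths; default [lpc_bandwidth()] of `scores`.
#' @param tol mean-shift movement threshold; default `1e-4 * mean(h)`.
#' @param max_iter mean-shift iteration cap (default 500).
#' @return Length-p numeric starting point.
#' @export
choose_start <- function(scores, reference = NULL, h = NULL,
                         tol = NULL, max_iter = 500L) {
  scores <- as.matrix(scores)
  if (!nrow(scores)) abort_argument("`scores` is empty")
  if (!is.null(reference) && length(reference) &&
      (!is.logical(reference) || any(reference))) {
    return(colMeans(scores[reference, , drop = FALSE]))
  }
  h <- h %||% lpc_bandwidth(scores)
  tol <- tol %||% (1e-4 * mean(h))
  dens <- vapply(seq_len(nrow(scores)),
                 function(i) sum(kernel_mass(scores[i, ], scores, h)),
                 0)
  x <- scores[which.max(dens), ]
  for (it in seq_len(max_iter)) {
    mu <- local_center_of_mass(x, scores, h)
    if (vec_norm(mu - x) < tol) return(mu)
    x <- mu
  }
  x
}
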