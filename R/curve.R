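#' Cumulative chord-length parameterization of a center sequence
#'
#' s_1 = 0 and s_l = s_{l-1} + ||mu_l - mu_{l-1}||. Duplicate consecutive
#' centers are dropped with a warning before accumulating so the result is
#' strictly increasing.
#'
#' @param centers numeric matrix of ordered points (rows).
#' @return List with `s` (strictly increasing chord lengths starting at 0)
#'   and `centers` (the possibly de-duplicated matrix).
#' @export
cumulative_chord <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) abort_argument("need >= 2 centers")
  d <- sqrt(rowSums((centers[-1L, , drop = FALSE] -
                       centers[-nrow(centers), , drop = FALSE])^2))
  if (any(d <= 1e-12)) {
    warning(sprintf("dropped %d duplicate consecutive center(s)", sum(d <= 1e-12)))
    centers <- centers[c(TRUE, d > 1e-12), , drop = FALSE]
    if (nrow(centers) < 2L) abort_argument("fewer than 2 distinct centers")
    d <- d[d > 1e-12]
  }
  list(s = c(0, cumsum(d)), centers = centers)
}

## Composite-Simpson arc-length increment of a speed function over [a, b].
simpson <- function(speed, a, b) {
  if (b <= a) return(0)
  (b - a) / 6 * (speed(a) + 4 * speed((a + b) / 2) + speed(b))
}

#' Interpolate LPC centers into an arc-length-parameterized curve
#'
#' Each coordinate is interpolated over the cumulative chord parameter `s` by
#' a natural cubic spline (linear interpolation when fewer than 4 centers are
#' available). The arc-length parameter
#' t(s) = integral_0^s sqrt(sum_j mu_j'(u)^2) du is tabulated on a dense grid
#' (`grid_per_interval` subdivisions per knot interval, Simpson quadrature per
#' cell) and is strictly increasing. The origin (`t = 0`) is set later by
#' [set_origin()].
#'
#' @param centers numeric matrix of ordered curve centers (rows), e.g.
#'   `fit_lpc(...)$centers`.
#' @param grid_per_interval dense-grid subdivisions per knot interval
#'   (default 50).
#' @return An object of class `lpc_curve`: knots, per-coordinate spline
#'   functions, the (s, t) arc table with curve points, end tangents used for
#'   projection beyond the ends, and `origin_t` (initially 0).
#' @export
parameterize_curve <- function(centers, grid_per_interval = 50L) {
  cc <- cumulative_chord(centers)
  centers <- cc$centers
  s <- cc$s
  L <- nrow(centers)
  p <- ncol(centers)
  cubic <- L >= 4L
  splines <- lapply(seq_len(p), function(j) {
    if (cubic) splinefun(s, centers[, j], method = "natural")
    else approxfun(s, centers[, j], rule = 2)
  })
  grid_per_interval <- max(2L, as.integer(grid_per_interval))
  s_grid <- unique(unlist(lapply(seq_len(L - 1L), function(l)
    seq(s[l], s[l + 1L], length.out = grid_per_interval + 1L))))
  s_grid <- sort(s_grid)
  pts <- vapply(splines, function(f) f(s_grid), numeric(length(s_grid)))
  if (cubic) {
    speed <- function(u) {
      du <- vapply(splines, function(f) f(u, deriv = 1), numeric(length(u)))
      if (is.null(dim(du))) sqrt(sum(du^2)) else sqrt(rowSums(du^2))
    }
    ## composite Simpson per grid cell, evaluated in one vectorized sweep
    m <- length(s_grid)
    v_grid <- speed(s_grid)
    v_mid <- speed((s_grid[-m] + s_grid[-1L]) / 2)
    inc <- diff(s_grid) / 6 * (v_grid[-m] + 4 * v_mid + v_grid[-1L])
    t_grid <- c(0, cumsum(inc))
  } else {
    ## linear interpolation over chord length moves at unit speed: t(s) = s
    speed <- NULL
    t_grid <- s_grid
  }
  if (any(diff(t_grid) <= 0))
    abort("arc-length parameter is not strictly increasing", "lpcscore_internal_error")
  ## unit tangents at the two ends, for projections beyond the curve support
  tangent <- function(at, towards) {
    if (cubic) {
      d <- vapply(splines, function(f) f(at, deriv = 1), 0)
      if (vec_norm(d) > 0) return(unit(d))
    }
    unit(towards)
  }
  t0 <- tangent(s[1L], centers[2L, ] - centers[1L, ])
  t1 <- tangent(s[L], centers[L, ] - centers[L - 1L, ])
  structure(
    list(knots_s = s, centers = centers, splines = splines, cubic = cubic,
         speed = speed, s_grid = s_grid, t_grid = t_grid, points = pts,
         p = p, origin_t = 0,
         end_points = list(lower = centers[1L, ], upper = centers[L, ]),
         end_tangents = list(lower = t0, upper = t1)),
    class = "lpc_curve")
}

#' Evaluate the curve at chord parameter values
#'
#' @param curve an `lpc_curve`.
#' @param s chord-parameter values (clamped to the spline support).
#' @return Matrix of curve points, one row per `s`.
#' @export
curve_point <- function(curve, s) {
  s <- pmin(pmax(s, curve$knots_s[1L]), curve$knots_s[length(curve$knots_s)])
  out <- vapply(curve$splines, function(f) f(s), numeric(length(s)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(s))
  out
}

## Arc length t at an off-grid chord value, via the nearest tabulated grid
## point plus a Simpson correction (exact for the linear case where t = s).
arc_at <- function(curve, s_val) {
  if (!curve$cubic) return(s_val)
  m <- length(curve$s_grid)
  s_val <- min(max(s_val, curve$s_grid[1L]), curve$s_grid[m])
  j <- findInterval(s_val, curve$s_grid, all.inside = TRUE)
  curve$t_grid[j] + simpson(curve$speed, curve$s_grid[j], s_val)
}

#' Project a point onto the parameterized curve
#'
#' Finds the nearest curve point in Euclidean distance over the dense arc
#' table, refined by bounded scalar minimization in the best grid cell
#' (`refine = TRUE`). Queries lying beyond the curve's ends are projected onto
#' the linear tangent extension of the end segments (standard principal-curve
#' practice; it keeps boundary samples distinguishable instead of collapsing
#' them onto the endpoints). Ties are broken toward smaller t.
#'
#' @param curve an `lpc_curve`.
#' @param x query point (length-p numeric).
#' @param refine refine within the best grid cell with [stats::optimize()]?
#' @param extend allow projections on the tangent extensions beyond the ends?
#' @return List with `t` (signed arc-length index relative to the curve
#'   origin) and `distance` (Euclidean distance to the curve).
#' @export
project_point <- function(curve, x, refine = TRUE, extend = TRUE,
                          .best = NULL, .best_d2 = NULL) {
  if (is.null(.best)) {
    d2 <- colSums((t(curve$points) - x)^2)
    i <- which.min(d2)
    d2_best <- d2[i]
  } else {
    i <- .best
    d2_best <- max(.best_d2, 0)
  }
  m <- length(curve$s_grid)
  s_best <- curve$s_grid[i]
  if (refine && m > 1L) {
    lo <- curve$s_grid[max(i - 1L, 1L)]
    hi <- curve$s_grid[min(i + 1L, m)]
    if (hi > lo) {
      opt <- optimize(function(s) sum((curve_point(curve, s)[1L, ] - x)^2),
                      interval = c(lo, hi),
                      tol = .Machine$double.eps^0.5 * (hi - lo) + 1e-14)
      if (opt$objective < d2_best) {
        s_best <- opt$minimum
        d2_best <- opt$objective
      }
    }
  }
  t_best <- arc_at(curve, s_best)
  dist_best <- sqrt(d2_best)
  if (extend) {
    q_lo <- sum((x - curve$end_points$lower) * curve$end_tangents$lower)
    if (q_lo < 0) {
      d_lo <- vec_norm(x - (curve$end_points$lower + q_lo * curve$end_tangents$lower))
      ## extension candidate has smaller t than any interior point
      if (d_lo <= dist_best) {
        t_best <- curve$t_grid[1L] + q_lo
        dist_best <- d_lo
      }
    }
    q_hi <- sum((x - curve$end_points$upper) * curve$end_tangents$upper)
    if (q_hi > 0) {
      d_hi <- vec_norm(x - (curve$end_points$upper + q_hi * curve$end_tangents$upper))
      if (d_hi < dist_best) {
        t_best <- curve$t_grid[length(curve$t_grid)] + q_hi
        dist_best <- d_hi
      }
    }
  }
  list(t = t_best - curve$origin_t, distance = dist_best)
}

#' Anchor the curve's origin at a point's projection
#'
#' Sets t = 0 at the projection of `f0` (typically the curve's starting
#' point, i.e. the reference centroid); all subsequently reported projection
#' indices are relative to it. When `f0` projects to the curve's start this
#' reduces to raw arc length.
#'
#' @param curve an `lpc_curve`.
#' @param f0 anchor point (length-p numeric).
#' @return The curve with `origin_t` set.
#' @export
set_origin <- function(curve, f0) {
  curve$origin_t <- 0
  pr <- project_point(curve, f0)
  curve$origin_t <- pr$t
  curve
}

#' Total arc length of the fitted curve
#' @param curve an `lpc_curve`.
#' @return The arc length t(s_max).
#' @export
arc_length <- function(curve) {
  curve$t_grid[length(curve$t_grid)]
}
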