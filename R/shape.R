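#' Cross-sectional shape parameters
#'
#' The vessel cross-section is modelled as two half-superellipses joined at
#' the horizontal line through the midpoint: a dorsal half with semi-axes
#' `c` (lateral) and `a` (dorsal) and exponent `alpha`, and a ventral half
#' with semi-axes `c` and `b` (ventral) and exponent `beta`. Points on the
#' dorsal half satisfy `|x/c|^(2/alpha) + |y/a|^(2/alpha) = 1` (midpoint at
#' the origin); `alpha = 1` gives an ellipse and smaller values approach a
#' rectangle, which captures dorsal flattening of the vessel. Exponents are
#' restricted to `[0.05, 2]` so the curve stays simple and numerically
#' well-behaved (the implicit exponent `2/alpha >= 1` also keeps each half
#' convex).
#'
#' @param m_x,m_y midpoint coordinates (micrometres).
#' @param a dorsal semi-axis (um), > 0.
#' @param b ventral semi-axis (um), > 0.
#' @param c lateral semi-axis (um), > 0.
#' @param alpha,beta dorsal/ventral exponents, in `[0.05, 2]`.
#' @return Named numeric vector of class `shape_params` with elements
#'   `m_x, m_y, a, b, c, alpha, beta`.
#' @export
shape_params <- function(m_x = 0, m_y = 0, a = 1, b = 1, c = 1,
                         alpha = 1, beta = 1) {
  theta <- c(m_x = m_x, m_y = m_y, a = a, b = b, c = c,
             alpha = alpha, beta = beta)
  validate_shape_params(theta)
  structure(theta, class = "shape_params")
}

shape_exponent_bounds <- c(0.05, 2)

validate_shape_params <- function(theta) {
  if (!all(is.finite(theta)) || length(theta) != 7L)
    stop("shape parameters must be 7 finite numbers", call. = FALSE)
  if (any(theta[c("a", "b", "c")] <= 0))
    stop("semi-axes a, b, c must be positive", call. = FALSE)
  ab <- theta[c("alpha", "beta")]
  if (any(ab < shape_exponent_bounds[1] - 1e-12) ||
      any(ab > shape_exponent_bounds[2] + 1e-12))
    stop(sprintf("exponents must lie in [%g, %g]", shape_exponent_bounds[1],
                 shape_exponent_bounds[2]), call. = FALSE)
  invisible(theta)
}

as_shape_params <- function(theta) {
  if (inherits(theta, "shape_params")) return(theta)
  theta <- as.numeric(theta)
  names(theta) <- c("m_x", "m_y", "a", "b", "c", "alpha", "beta")
  validate_shape_params(theta)
  structure(theta, class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat("Joined half-superellipse cross-section\n")
  cat(sprintf("  midpoint (%.3f, %.3f) um; semi-axes a=%.3f b=%.3f c=%.3f um\n",
              x["m_x"], x["m_y"], x["a"], x["b"], x["c"]))
  cat(sprintf("  exponents alpha=%.3f (dorsal), beta=%.3f (ventral)\n",
              x["alpha"], x["beta"]))
  invisible(x)
}

#' Evaluate the cross-sectional shape
#'
#' Trigonometric parameterisation of the joined half-superellipse. The
#' parameter `u` runs counter-clockwise: `u` in `[0, pi]` covers the dorsal
#' half (`y >= m_y`), `u` in `(pi, 2*pi]` the ventral half. At `u = 0, pi,
#' 2*pi` the curve passes through `(m_x +/- c, m_y)` so the two halves join
#' continuously.
#'
#' @param theta shape parameters ([shape_params()]).
#' @param u numeric vector of parameters in `[0, 2*pi]`.
#' @return n x 2 matrix of points (x, y).
#' @export
shape_evaluate <- function(theta, u) {
  theta <- as_shape_params(theta)
  if (any(u < -1e-12 | u > 2 * pi + 1e-12))
    stop("parameter u must lie in [0, 2*pi]", call. = FALSE)
  u <- pmin(pmax(u, 0), 2 * pi)
  dorsal <- u <= pi
  expo <- ifelse(dorsal, theta[["alpha"]], theta[["beta"]])
  cu <- cos(u)
  su <- sin(u)
  # snap floating-point residues of cos/sin at the axis parameters: for
  # small exponents, |1e-16|^alpha would otherwise be far from the axis
  cu[abs(cu) < 1e-12] <- 0
  su[abs(su) < 1e-12] <- 0
  x <- theta[["m_x"]] + theta[["c"]] * sign(cu) * abs(cu)^expo
  y <- ifelse(dorsal,
              theta[["m_y"]] + theta[["a"]] * abs(su)^expo,
              theta[["m_y"]] - theta[["b"]] * abs(su)^expo)
  cbind(x = x, y = y)
}

#' Polygon approximation of a shape
#'
#' Vertices at `n_poly` linearly spaced parameter values in `[0, 2*pi)`.
#'
#' @inheritParams shape_evaluate
#' @param n_poly number of vertices (>= 16).
#' @return n_poly x 2 matrix of vertices in counter-clockwise order.
#' @export
shape_polygon <- function(theta, n_poly = 360L) {
  if (n_poly < 16L) stop("n_poly must be >= 16", call. = FALSE)
  u <- seq(0, 2 * pi, length.out = n_poly + 1L)[-(n_poly + 1L)]
  shape_evaluate(theta, u)
}

#' Project a point onto a shape
#'
#' The Euclidean distance to a general superellipse has no closed form, so the
#' curve is approximated by a dense polygon and the point projected
#' orthogonally onto the polygon's edges (clamped to segments).
#'
#' @inheritParams shape_evaluate
#' @param p_xy a single 2D point or an n x 2 matrix of points.
#' @param n_poly polygon density (>= 16).
#' @return A list with `point` (n x 2 matrix of closest points) and
#'   `distance` (numeric vector).
#' @export
shape_project <- function(theta, p_xy, n_poly = 360L) {
  poly <- shape_polygon(theta, n_poly)
  p_xy <- matrix(as.numeric(p_xy), ncol = 2L)
  res <- .proj_polygon_cpp(p_xy, poly, TRUE)
  list(point = res[, 2:3, drop = FALSE], distance = res[, 1])
}

# Speed |phi'(u)| of one superellipse quarter with semi-axes (half_y, c) and
# exponent e, u in (0, pi/2). Singular but integrable at the endpoints when
# e < 1.
quarter_speed <- function(u, half_y, c_ax, e) {
  su <- sin(u); cu <- cos(u)
  dx <- c_ax * e * abs(cu)^(e - 1) * su
  dy <- half_y * e * abs(su)^(e - 1) * cu
  sqrt(dx^2 + dy^2)
}

#' Circumference of a shape
#'
#' Arc length of the joined half-superellipse, computed by adaptive quadrature
#' of the analytic speed on each quarter (the integrand can be unbounded at
#' the quarter endpoints for exponents < 1, which the adaptive rule handles).
#'
#' @inheritParams shape_evaluate
#' @return Circumference in micrometres.
#' @export
shape_circumference <- function(theta) {
  theta <- as_shape_params(theta)
  q <- function(half_y, e) {
    stats::integrate(quarter_speed, 0, pi / 2, half_y = half_y,
                     c_ax = theta[["c"]], e = e,
                     rel.tol = 1e-9, subdivisions = 400L)$value
  }
  2 * (q(theta[["a"]], theta[["alpha"]]) + q(theta[["b"]], theta[["beta"]]))
}

# Dense arc-length table for a shape: parameters u, points, cumulative chord
# arc length. The parameter speed is unbounded at multiples of pi/2 for
# exponents < 1, so segments longer than a small fraction of the
# circumference are bisected adaptively until the table is uniformly fine
# in arc length.
shape_arc_table <- function(theta, tol_frac = 5e-5, max_pts = 65536L) {
  u <- seq(0, 2 * pi, length.out = 1025L)
  pts <- shape_evaluate(theta, u)
  repeat {
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-length(u), , drop = FALSE])^2))
    tol <- tol_frac * sum(seg)
    bad <- which(seg > tol)
    if (length(bad) == 0L || length(u) + length(bad) > max_pts) break
    umid <- (u[bad] + u[bad + 1L]) / 2
    pmid <- shape_evaluate(theta, umid)
    u <- c(u, umid)
    pts <- rbind(pts, pmid)
    ord <- order(u)
    u <- u[ord]
    pts <- pts[ord, , drop = FALSE]
  }
  list(u = u, pts = pts, cum = c(0, cumsum(seg)))
}

#' Equidistant points on a shape
#'
#' Computes `n_k = floor(n_cross_rel * circumference)` points equally spaced
#' in arc length, the first at parameter `u = 0`.
#'
#' @inheritParams shape_evaluate
#' @param n_cross_rel relative number of points per micrometre of
#'   circumference.
#' @param n_k optionally override the point count directly.
#' @return List with `points` (n_k x 2), `u` (parameters, strictly increasing
#'   from 0), and `circumference`.
#' @export
shape_equidistant <- function(theta, n_cross_rel = 2, n_k = NULL) {
  theta <- as_shape_params(theta)
  tab <- shape_arc_table(theta)
  circ <- tab$cum[length(tab$cum)]
  if (is.null(n_k)) n_k <- floor(n_cross_rel * circ)
  if (n_k < 8L) stop("cross-section resolution too low (n_k < 8)", call. = FALSE)
  s_targets <- (seq_len(n_k) - 1L) / n_k * circ
  u <- stats::approx(tab$cum, tab$u, xout = s_targets, ties = "ordered")$y
  u[1] <- 0
  list(points = shape_evaluate(theta, u), u = u, circumference = circ)
}

#' Area enclosed by a shape
#'
#' Shoelace area of a dense polygon approximation (or of a polygon passed
#' directly).
#'
#' @param x shape parameters or an n x 2 polygon matrix.
#' @param n_poly polygon density used when `x` is a parameter vector.
#' @return Positive area in um^2.
#' @export
shape_area <- function(x, n_poly = 3600L) {
  poly <- if (inherits(x, "shape_params") ||
              (is.numeric(x) && is.null(dim(x)) && length(x) == 7L))
    shape_polygon(as_shape_params(x), n_poly)
  else as_poly_matrix(x)
  polygon_area(poly)
}

#' Relative cross-sectional shape deviation
#'
#' Area of the symmetric difference of two cross-sectional shapes, normalised
#' by the area of the reference shape: `area(phi symdiff ref) / area(ref)`.
#' Zero iff the curves coincide; not symmetric in its arguments (the
#' denominator is the reference). Shapes are compared as polygons; the
#' symmetric difference is `area(A) + area(B) - 2 * area(A intersect B)`.
#'
#' @param phi shape parameters or polygon (n x 2 matrix).
#' @param phi_ref reference shape parameters or polygon.
#' @param n_poly polygon density for parameter inputs.
#' @return Non-negative fraction.
#' @export
dev_cross <- function(phi, phi_ref, n_poly = 360L) {
  to_poly <- function(x) {
    if (inherits(x, "shape_params") ||
        (is.numeric(x) && is.null(dim(x)) && length(x) == 7L))
      shape_polygon(as_shape_params(x), n_poly)
    else as_poly_matrix(x)
  }
  A <- to_poly(phi)
  B <- to_poly(phi_ref)
  area_a <- polygon_area(A)
  area_b <- polygon_area(B)
  if (area_b <= 0) stop("degenerate reference shape", call. = FALSE)
  inter <- polygon_intersection_area(A, B)
  dev <- (area_a + area_b - 2 * inter) / area_b
  max(dev, 0)
}
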