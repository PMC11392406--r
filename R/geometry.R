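#' @useDynLib lumenfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Area of a simple polygon
#'
#' Shoelace area of a closed polygon given as an n x 2 matrix of vertices in
#' order (first vertex not repeated). The result is positive regardless of
#' orientation.
#'
#' @param poly numeric matrix with 2 columns, n >= 3 rows.
#' @return Positive area (squared input units).
#' @export
polygon_area <- function(poly) {
  poly <- as_poly_matrix(poly)
  abs(.polygon_area_signed_cpp(poly))
}

as_poly_matrix <- function(poly) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  if (ncol(poly) < 2L || nrow(poly) < 3L)
    stop("polygon needs >= 3 vertices with 2 coordinates", call. = FALSE)
  poly[, 1:2, drop = FALSE]
}

# Orient polygon counter-clockwise (positive signed area).
orient_ccw <- function(poly) {
  if (.polygon_area_signed_cpp(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

# Convexity test with a relative tolerance; polygon must be oriented CCW.
is_convex_polygon <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  e <- poly[nxt, , drop = FALSE] - poly
  nxt2 <- c(2:n, 1L)
  cr <- e[, 1] * e[nxt2, 2] - e[, 2] * e[nxt2, 1]
  scale <- max(abs(e))^2
  all(cr >= -tol * scale)
}

# Simplicity (non-self-intersection) check by brute-force segment pairs.
# O(n^2); used only in validation paths on modest polygons.
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  p1 <- poly
  p2 <- poly[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(a, b, c, d) {
  o <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    sign(v)
  }
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && on_segment(a, b, c)) || (o2 == 0 && on_segment(a, b, d)) ||
    (o3 == 0 && on_segment(c, d, a)) || (o4 == 0 && on_segment(c, d, b))
}

on_segment <- function(a, b, p) {
  p[1] <= max(a[1], b[1]) && p[1] >= min(a[1], b[1]) &&
    p[2] <= max(a[2], b[2]) && p[2] >= min(a[2], b[2])
}

# Intersection area of two simple polygons. Exact (Sutherland-Hodgman) when
# `clip` is convex; otherwise a deterministic raster approximation on an
# n_grid x n_grid lattice over the joint bounding box.
polygon_intersection_area <- function(subject, clip, n_grid = 512L) {
  subject <- orient_ccw(as_poly_matrix(subject))
  clip <- orient_ccw(as_poly_matrix(clip))
  if (is_convex_polygon(clip)) {
    inter <- .clip_polygon_convex_cpp(subject, clip)
    if (nrow(inter) < 3L) return(0)
    return(abs(.polygon_area_signed_cpp(inter)))
  }
  if (is_convex_polygon(subject)) {
    inter <- .clip_polygon_convex_cpp(clip, subject)
    if (nrow(inter) < 3L) return(0)
    return(abs(.polygon_area_signed_cpp(inter)))
  }
  rng_x <- range(subject[, 1], clip[, 1])
  rng_y <- range(subject[, 2], clip[, 2])
  gx <- seq(rng_x[1], rng_x[2], length.out = n_grid)
  gy <- seq(rng_y[1], rng_y[2], length.out = n_grid)
  pts <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  ins <- .points_in_polygon_cpp(pts, subject) & .points_in_polygon_cpp(pts, clip)
  cell <- (diff(rng_x) / (n_grid - 1)) * (diff(rng_y) / (n_grid - 1))
  sum(ins) * cell
}

# --- rigid transforms -------------------------------------------------------

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector.
#' @return An object of class `rigid_transform`: applies `p %*% t(R) + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param pts n x 3 matrix of points.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, pts) {
  pts <- as.matrix(pts)
  sweep(pts %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", format(x$translation, digits = 6), "\n")
  invisible(x)
}

# Compose: apply `a` after `b`, i.e. (a o b)(p) = a(b(p)).
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

invert_transform <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

# Rotation matrix from axis angles (XYZ intrinsic small-angle composition).
rotation_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

# Angle (degrees) between two rotations.
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  R <- crossprod(R2, R1)
  cosang <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Random rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Least-squares plane through 3D points: returns list(point, normal).
fit_plane <- function(pts) {
  pts <- as.matrix(pts)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  list(point = ctr, normal = sv$v[, 3])
}
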