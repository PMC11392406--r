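#' Luminal area of a cross-section ring
#'
#' Shoelace area of the polygon enclosed by the ring's points in the
#' cross-sectional plane (positive regardless of orientation).
#'
#' @param ring a grid ring (list with `points`) or an n x 2/3 point matrix.
#' @param check verify simplicity (non-self-intersection) of the polygon.
#' @return Area (um^2).
#' @export
luminal_area <- function(ring, check = TRUE) {
  pts <- ring_points_xy(ring)
  if (check && !is_simple_polygon_fast(pts))
    stop("self-intersecting cross-section polygon", call. = FALSE)
  polygon_area(pts)
}

ring_points_xy <- function(ring) {
  pts <- if (is.list(ring) && !is.null(ring$points)) ring$points else ring
  as.matrix(pts)[, 1:2, drop = FALSE]
}

# Vectorised O(n^2) segment-pair intersection test.
is_simple_polygon_fast <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  a <- poly; b <- poly[nxt, , drop = FALSE]
  pr <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1L &
                      !(i == 1L & j == n)), arr.ind = TRUE)
  if (nrow(pr) == 0L) return(TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  d <- function(p, q, r) {
    (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) - (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  }
  o1 <- sign(d(a[i, , drop = FALSE], b[i, , drop = FALSE], a[j, , drop = FALSE]))
  o2 <- sign(d(a[i, , drop = FALSE], b[i, , drop = FALSE], b[j, , drop = FALSE]))
  o3 <- sign(d(a[j, , drop = FALSE], b[j, , drop = FALSE], a[i, , drop = FALSE]))
  o4 <- sign(d(a[j, , drop = FALSE], b[j, , drop = FALSE], b[i, , drop = FALSE]))
  !any(o1 != o2 & o3 != o4 & o1 != 0 & o3 != 0)
}

#' Luminal diameter of a cross-section ring
#'
#' Maximal pairwise distance between ring points.
#'
#' @param ring a grid ring or point matrix (>= 2 points).
#' @return Diameter (um).
#' @export
luminal_diameter <- function(ring) {
  pts <- if (is.list(ring) && !is.null(ring$points)) ring$points else ring
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) stop("need >= 2 points", call. = FALSE)
  max(stats::dist(pts))
}

#' Cell surface area, perimeter and compactness
#'
#' Surface area is the sum of the mesh triangle areas; the perimeter is the
#' total length of the projected contour's edges (closed); compactness is
#' `4*pi*area / perim^2`, the ratio of the cell's area to that of a circle
#' with the same perimeter (1 for a circle).
#'
#' @param mesh a `cell_mesh`.
#' @return Area (um^2).
#' @export
cell_area <- function(mesh) mesh_area(mesh)

#' @rdname cell_area
#' @param proj a `projected_contour` (or any closed point sequence).
#' @return Perimeter (um).
#' @export
cell_perimeter <- function(proj) {
  pts <- if (is.list(proj) && !is.null(proj$points)) proj$points else as.matrix(proj)
  contour_perimeter(pts)
}

#' @rdname cell_area
#' @param area,perim area and perimeter.
#' @return Compactness (dimensionless; 1 for a circle). Values above 1 can
#'   only arise from numeric mesh artefacts and are reported with a warning.
#' @export
compactness <- function(area, perim) {
  if (perim <= 0) stop("perimeter must be positive", call. = FALSE)
  cp <- 4 * pi * area / perim^2
  if (any(cp > 1 + 1e-9))
    warning("compactness > 1: degenerate mesh or perimeter")
  cp
}

# Angles/radii of points about the per-ring shape midpoints.
cell_polar <- function(keys, vertices, grid) {
  mids <- t(vapply(grid$rings, function(r) r$theta[c("m_x", "m_y")],
                   numeric(2)))
  m <- mids[keys[, 1], , drop = FALSE]
  dx <- vertices[, 1] - m[, 1]
  dy <- vertices[, 2] - m[, 2]
  list(angle = atan2(dy, dx) %% (2 * pi), radius = sqrt(dx^2 + dy^2))
}

# Smallest circular arc covering a set of angles; 2*pi when the points wrap
# all the way around.
angular_span <- function(angles) {
  a <- sort(angles %% (2 * pi))
  gaps <- diff(c(a, a[1] + 2 * pi))
  2 * pi - max(gaps)
}

#' Cell elongation in the direction of flow
#'
#' Ratio of the cell's bounding-box extension along the vessel axis (z) to
#' its extension within the cross-sectional plane. The cross-sectional
#' extension is the arc length of the smallest circular arc (about the
#' per-plane shape midpoints) covering the cell's angular range, at the
#' cell's median radial distance. A cell wrapping the full circumference
#' uses the full circle at the median radius and is flagged.
#'
#' @param mesh a `cell_mesh`.
#' @param grid the [build_grid()] result.
#' @return List: `elong`, `dz`, `span` (radians), `median_radius`,
#'   `wraps` (logical).
#' @export
elongation <- function(mesh, grid) {
  zr <- range(mesh$vertices[, 3])
  if (diff(zr) <= 0) stop("cell must span >= 2 planes", call. = FALSE)
  pol <- cell_polar(mesh$keys, mesh$vertices, grid)
  span <- angular_span(pol$angle)
  med_r <- stats::median(pol$radius)
  # full wrap: the largest angular gap is comparable to the typical gap
  # between neighbouring covered directions (no empty sector remains)
  a <- sort(unique(round(pol$angle %% (2 * pi), 9)))
  gaps <- diff(c(a, a[1] + 2 * pi))
  wraps <- max(gaps) < 4 * stats::quantile(gaps, 0.9) + 1e-12
  denom <- if (wraps) 2 * pi * med_r else span * med_r
  list(elong = diff(zr) / denom, dz = diff(zr), span = span,
       median_radius = med_r, wraps = wraps)
}

sector_names <- c("dorsal", "ventral", "left", "right")

# Sector of angles (radians, about midpoint, +y dorsal): 90-degree quadrants
# split on the +-45-degree diagonals; boundary angles go to the
# counter-clockwise-next sector.
sector_of <- function(angle) {
  a <- angle %% (2 * pi)
  idx <- floor(((a - pi / 4) %% (2 * pi)) / (pi / 2)) + 1L
  # idx 1: (45,135] -> dorsal; 2: (135,225] -> left; 3: (225,315] -> ventral;
  # 4: (315,45] -> right   (floor => lower boundary inclusive, CCW-next)
  c("dorsal", "left", "ventral", "right")[idx]
}

#' Classify a cell by its location on the vessel circumference
#'
#' Each triangle is assigned to the dorsal, ventral, left or right sector
#' (90-degree quadrants about the per-plane shape midpoint, dorsal up,
#' boundaries on the diagonals) containing its centroid; sector fractions
#' are area fractions. A cell is dorsal (ventral) if that sector holds more
#' than 50% of its area, left/right if either lateral sector alone does, and
#' unclassified otherwise. The detailed label merges left+right: a single
#' label (D/V/LR) needs more than 75% of the area; between 50% and 75% a
#' compound label appends the sector(s) holding at least half of the
#' remaining area, ordered by fraction; otherwise NA.
#'
#' @param mesh a `cell_mesh`.
#' @param grid the [build_grid()] result.
#' @return List: `fractions` (named: dorsal, ventral, left, right), `class`,
#'   `detailed`.
#' @export
classify_cell <- function(mesh, grid) {
  tri <- mesh$triangles
  cent <- (mesh$vertices[tri[, 1], , drop = FALSE] +
             mesh$vertices[tri[, 2], , drop = FALSE] +
             mesh$vertices[tri[, 3], , drop = FALSE]) / 3
  # nearest ring midpoint for each centroid
  zs <- vapply(grid$rings, function(r) r$z, numeric(1))
  kk <- vapply(cent[, 3], function(z) which.min(abs(zs - z)), integer(1))
  pol <- cell_polar(cbind(kk, 1L), cent, grid)
  sec <- sector_of(pol$angle)
  ar <- triangle_areas(mesh$vertices, tri)
  tot <- sum(ar)
  fr <- vapply(sector_names, function(s) sum(ar[sec == s]) / tot, numeric(1))
  cls <- if (fr[["dorsal"]] > 0.5) "dorsal"
  else if (fr[["ventral"]] > 0.5) "ventral"
  else if (fr[["left"]] > 0.5 || fr[["right"]] > 0.5) "left/right"
  else "unclassified"
  g <- c(D = fr[["dorsal"]], V = fr[["ventral"]],
         LR = fr[["left"]] + fr[["right"]])
  g <- sort(g, decreasing = TRUE)
  detailed <- if (g[1] > 0.75) names(g)[1]
  else if (g[1] > 0.5) {
    rem <- 1 - g[1]
    suf <- names(g)[-1][g[-1] >= rem / 2 & g[-1] > 0]
    if (length(suf) == 0L) names(g)[1]
    else paste(c(names(g)[1], suf), collapse = "-")
  } else NA_character_
  list(fractions = fr, class = cls, detailed = detailed)
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with quartiles by linear interpolation (type 7);
#' a scale-free measure of within-sample variability.
#'
#' @param values numeric vector of at least 4 positive values.
#' @return List with `Q1`, `Q3`, `qcd`.
#' @export
qcd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L || any(values <= 0))
    stop("qcd needs >= 4 positive values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (sum(q) == 0) stop("Q1 + Q3 is zero", call. = FALSE)
  list(Q1 = q[1], Q3 = q[2], qcd = (q[2] - q[1]) / (q[2] + q[1]))
}

#' Relative deviation of an altered measurement
#'
#' `(altered - reference) / altered`: the signed fraction by which the
#' reference falls short of (negative) or exceeds (positive) the altered
#' value, with the altered value as the denominator.
#'
#' @param altered,reference numeric (altered must be non-zero).
#' @return Signed fraction.
#' @export
dev_rel <- function(altered, reference) {
  if (any(altered == 0)) stop("altered value must be non-zero", call. = FALSE)
  (altered - reference) / altered
}

#' Exclusion filter on cells
#'
#' Keeps cells whose annotated-vs-projected contour distance does not exceed
#' the maximal annotation uncertainty.
#'
#' @param cells data.frame with columns `cell_id` and `projection_distance`.
#' @param max_projection_distance threshold (um; default 0.742).
#' @return List with data.frames `kept` and `excluded`.
#' @export
filter_cells <- function(cells, max_projection_distance = 0.742) {
  keep <- cells$projection_distance <= max_projection_distance
  list(kept = cells[keep, , drop = FALSE],
       excluded = cells[!keep, , drop = FALSE])
}

#' Exclusion filter on cross-sections
#'
#' Keeps a plane only if at least `min_cells` distinct annotated cells have
#' at least one contour point within `radius_z` of the plane.
#'
#' @param z plane positions.
#' @param contours list of annotated contours (in the same frame as `z`,
#'   i.e. vessel coordinates).
#' @param min_cells minimum number of nearby cells (default 2).
#' @param radius_z axial distance threshold (um; default 0.5).
#' @return List: `kept` (indices), `excluded` (indices), `n_nearby`
#'   (per-plane cell counts).
#' @export
filter_cross_sections <- function(z, contours, min_cells = 2L, radius_z = 0.5) {
  zlists <- lapply(contours, function(ct) {
    pts <- if (is.list(ct) && !is.null(ct$points)) ct$points else ct
    range(as.matrix(pts)[, 3])
  })
  zpts <- lapply(contours, function(ct) {
    pts <- if (is.list(ct) && !is.null(ct$points)) ct$points else ct
    as.matrix(pts)[, 3]
  })
  n_nearby <- vapply(z, function(zk)
    sum(vapply(zpts, function(zz) any(abs(zz - zk) <= radius_z), logical(1))),
    numeric(1))
  keep <- which(n_nearby >= min_cells)
  list(kept = keep, excluded = setdiff(seq_along(z), keep),
       n_nearby = n_nearby)
}
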