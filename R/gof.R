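#' Distance from a point to a closed contour
#'
#' Minimal orthogonal distance from `p` to the line segments of contour `B`
#' (projections clamped to the segments).
#'
#' @param p length-3 point or n x 3 matrix of points.
#' @param B m x 3 matrix of contour points (m >= 2), treated as closed.
#' @param closed treat the contour as closed.
#' @return Distance(s) in um.
#' @export
point_to_contour_distance <- function(p, B, closed = TRUE) {
  p <- matrix(as.numeric(p), ncol = 3L)
  B <- as.matrix(B)
  if (nrow(B) < 2L) stop("contour B needs >= 2 points", call. = FALSE)
  as.numeric(.dist_polyline3_cpp(p, B, closed))
}

# Densify a closed polyline so consecutive gaps are <= spacing.
densify_contour <- function(pts, spacing) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]; q <- pts[nxt[i], ]
    len <- sqrt(sum((q - p)^2))
    k <- max(0L, ceiling(len / spacing) - 1L)
    if (k > 0) {
      fr <- seq_len(k) / (k + 1)
      out[[i]] <- rbind(p, outer(1 - fr, p) + outer(fr, q))
    } else out[[i]] <- matrix(p, nrow = 1)
  }
  do.call(rbind, out)
}

#' Symmetric contour-to-contour distance
#'
#' Both contours are densified by linear interpolation to point gaps of at
#' most `densify_spacing`; the asymmetric distance from A to B is the mean
#' of the point distances of (densified) A to (densified) B's segments, and
#' the symmetric distance is the maximum of the two asymmetric distances.
#' Outlier-insensitive, symmetric, zero only for coincident contours.
#'
#' @param A,B closed contours: n x 3 matrices or objects with `$points`.
#' @param densify_spacing maximal point gap after densification (um).
#' @return Distance in um.
#' @export
contour_distance <- function(A, B, densify_spacing = 0.1) {
  getpts <- function(x) {
    pts <- if (is.list(x) && !is.null(x$points)) x$points else x
    as.matrix(pts)
  }
  A <- getpts(A); B <- getpts(B)
  if (nrow(A) < 3L || nrow(B) < 3L)
    stop("degenerate contour (need >= 3 points)", call. = FALSE)
  stopifnot(densify_spacing > 0)
  Ad <- densify_contour(A, densify_spacing)
  Bd <- densify_contour(B, densify_spacing)
  dBA <- mean(.dist_polyline3_cpp(Ad, Bd, TRUE))
  dAB <- mean(.dist_polyline3_cpp(Bd, Ad, TRUE))
  max(dBA, dAB)
}

#' Projection distance of a cell
#'
#' Symmetric contour distance between a cell's manually annotated contour
#' (transformed into the estimated vessel frame) and its projection onto the
#' reconstructed vessel surface; the goodness-of-fit measure per cell.
#'
#' @param anno_transf annotated contour in vessel coordinates.
#' @param proj the cell's `projected_contour` (or point matrix).
#' @param densify_spacing see [contour_distance()].
#' @return Distance in um.
#' @export
projection_distance <- function(anno_transf, proj, densify_spacing = 0.1) {
  contour_distance(anno_transf, proj, densify_spacing)
}

#' Slice a triangle mesh with a plane
#'
#' Intersects the triangulated vessel surface with an arbitrary plane and
#' chains the intersection segments into a single closed polygon, returned
#' in 2D in-plane coordinates (y' aligned with the in-plane projection of
#' the dorsal direction).
#'
#' @param mesh a mesh (e.g. [grid_mesh()] output) in vessel coordinates.
#' @param plane list with `point` (length 3) and `normal` (length 3, need
#'   not be unit).
#' @param dorsal dorsal direction used to orient the in-plane axes.
#' @return List: `polygon_2d` (n x 2), `polygon_3d` (n x 3), `basis`
#'   (2 x 3 in-plane basis rows), `origin`.
#' @export
slice_mesh <- function(mesh, plane, dorsal = c(0, 1, 0)) {
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  d <- as.numeric(mesh$vertices %*% nrm) - sum(plane$point * nrm)
  tri <- mesh$triangles
  segs <- list()
  for (r in seq_len(nrow(tri))) {
    vi <- tri[r, ]
    dv <- d[vi]
    pos <- dv > 0
    if (all(pos) || all(!pos)) next
    pts <- matrix(0, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dv[e[1]]; d2 <- dv[e[2]]
      if ((d1 > 0) != (d2 > 0)) {
        t <- d1 / (d1 - d2)
        p1 <- mesh$vertices[vi[e[1]], ]
        p2 <- mesh$vertices[vi[e[2]], ]
        pts <- rbind(pts, p1 + t * (p2 - p1))
      }
    }
    # a vertex exactly on the plane yields coincident crossing points
    if (nrow(pts) > 2L)
      pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
    if (nrow(pts) == 2L && sum((pts[1, ] - pts[2, ])^2) > 1e-18)
      segs[[length(segs) + 1L]] <- pts
  }
  if (length(segs) < 3L)
    stop("plane does not intersect the surface transversally", call. = FALSE)
  # chain segments by matching endpoints
  keyof <- function(p) paste(round(p, 7), collapse = "|")
  ends <- lapply(segs, function(s) c(keyof(s[1, ]), keyof(s[2, ])))
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(segs)) for (j in 1:2) {
    k <- ends[[i]][j]
    assign(k, c(if (exists(k, lookup)) get(k, lookup), i), lookup)
  }
  used <- logical(length(segs))
  cur <- 1L
  used[1] <- TRUE
  loop <- list(segs[[1]][1, ], segs[[1]][2, ])
  cur_key <- ends[[1]][2]
  repeat {
    cands <- setdiff(get(cur_key, lookup), which(used))
    if (length(cands) == 0L) break
    nxt <- cands[1]
    used[nxt] <- TRUE
    which_end <- if (ends[[nxt]][1] == cur_key) 2L else 1L
    loop[[length(loop) + 1L]] <- segs[[nxt]][which_end, ]
    cur_key <- ends[[nxt]][which_end]
  }
  if (cur_key != ends[[1]][1])
    stop("slice is not a single closed loop", call. = FALSE)
  if (any(!used))
    stop("slice produced multiple loops", call. = FALSE)
  poly3 <- do.call(rbind, loop[-length(loop)])  # drop repeated closing point
  yin <- dorsal - sum(dorsal * nrm) * nrm
  if (sqrt(sum(yin^2)) < 1e-8) yin <- c(0, 0, 1) - sum(c(0, 0, 1) * nrm) * nrm
  yin <- yin / sqrt(sum(yin^2))
  xin <- cross3(yin, nrm)
  origin <- plane$point
  rel <- sweep(poly3, 2L, origin)
  poly2 <- cbind(as.numeric(rel %*% xin), as.numeric(rel %*% yin))
  list(polygon_2d = poly2, polygon_3d = poly3,
       basis = rbind(x = xin, y = yin), origin = origin)
}

#' Compare a surface slice with a reference slice
#'
#' Computes the shape deviation `dev_cross(S; S_ref)` (symmetric-difference
#' area over the reference area) and the relative luminal-area deviation
#' `dev_rel(area(S); area(S_ref))` between a vessel-surface slice and a
#' reference (e.g. angiogram) slice in the same plane.
#'
#' @param S surface slice: n x 2 polygon (or `slice_mesh()` output).
#' @param S_ref reference slice polygon, n x 2, same 2D frame.
#' @return List with `dev_cross` and `dev_rel_area`.
#' @export
compare_slices <- function(S, S_ref) {
  if (is.list(S) && !is.null(S$polygon_2d)) S <- S$polygon_2d
  S <- as_poly_matrix(S)
  S_ref <- as_poly_matrix(S_ref)
  list(dev_cross = dev_cross(S, S_ref),
       dev_rel_area = dev_rel(polygon_area(S), polygon_area(S_ref)))
}

#' Compare reconstructed surface against annotated angiogram slices
#'
#' For each annotated slice, fits its plane (least squares), slices the
#' reconstructed surface with that plane, expresses both outlines in the
#' same in-plane coordinates and reports shape and area deviations.
#'
#' @param mesh triangulated vessel surface in vessel coordinates.
#' @param slices list of n x 3 matrices of annotated slice points (already
#'   transformed into vessel coordinates).
#' @return data.frame: `slice`, `dev_cross`, `dev_rel_area`.
#' @export
validate_against_slices <- function(mesh, slices) {
  out <- lapply(seq_along(slices), function(i) {
    sl <- as.matrix(slices[[i]])
    pl <- fit_plane(sl)
    sm <- slice_mesh(mesh, pl)
    rel <- sweep(sl, 2L, sm$origin)
    ref2 <- cbind(as.numeric(rel %*% sm$basis[1, ]),
                  as.numeric(rel %*% sm$basis[2, ]))
    cmp <- compare_slices(sm$polygon_2d, ref2)
    data.frame(slice = i, dev_cross = cmp$dev_cross,
               dev_rel_area = cmp$dev_rel_area)
  })
  do.call(rbind, out)
}
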