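#' Project a cell contour spline onto the vessel grid
#'
#' Traverses the (transformed) cell contour spline and, at every crossing of
#' a cross-sectional plane, snaps the intersection point to its nearest
#' neighbour among the plane's precomputed equidistant ring points. Crossings
#' are located by sign changes of the spline's z-coordinate on a dense
#' parameter grid and refined by bisection. Consecutive duplicate references
#' are collapsed; the closed ordering is preserved.
#'
#' @param spline a `periodic_spline` in vessel coordinates.
#' @param grid a [build_grid()] result.
#' @param n_dense dense sampling resolution (defaults to 4x the spline's
#'   equidistant sample count, at least 512).
#' @return Object of class `projected_contour`: `cell_id`, `refs` (matrix
#'   with columns `k` (ring index) and `j` (point index)), `points` (realized
#'   3D grid points), `u` (crossing parameters).
#' @export
project_contour_to_grid <- function(spline, grid, n_dense = NULL) {
  if (is.null(n_dense))
    n_dense <- max(512L, 4L * floor(2 * spline$perimeter_chord))
  zs <- grid$z
  u <- seq(0, 1, length.out = n_dense + 1L)
  zu <- predict(spline, u)[, 3]
  if (max(zu) < min(zs) || min(zu) > max(zs) ||
      sum(zs >= min(zu) & zs <= max(zu)) < 2L)
    stop(sprintf("cell %s: spline spans fewer than 2 grid planes",
                 spline$cell_id), call. = FALSE)
  # all (segment, plane) crossings, half-open so a sample exactly on a plane
  # is counted once
  seg_lo <- zu[-(n_dense + 1L)]
  seg_hi <- zu[-1L]
  cross_seg <- integer(0); cross_k <- integer(0)
  for (k in seq_along(zs)) {
    hit <- (seg_lo <= zs[k] & zs[k] < seg_hi) |
      (seg_hi <= zs[k] & zs[k] < seg_lo)
    if (any(hit)) {
      cross_seg <- c(cross_seg, which(hit))
      cross_k <- c(cross_k, rep(k, sum(hit)))
    }
  }
  if (length(cross_seg) < 3L)
    stop(sprintf("cell %s: fewer than 3 plane crossings", spline$cell_id),
         call. = FALSE)
  # vectorised bisection on all crossings simultaneously
  ulo <- u[cross_seg]; uhi <- u[cross_seg + 1L]
  zlo <- zu[cross_seg]
  ztar <- zs[cross_k]
  for (it in 1:40) {
    umid <- (ulo + uhi) / 2
    zmid <- predict(spline, umid)[, 3]
    below <- (zlo <= ztar) == (zmid <= ztar)
    ulo <- ifelse(below, umid, ulo)
    zlo <- ifelse(below, zmid, zlo)
    uhi <- ifelse(below, uhi, umid)
  }
  ustar <- (ulo + uhi) / 2
  pts <- predict(spline, ustar)
  ord <- order(ustar)
  ustar <- ustar[ord]; pts <- pts[ord, , drop = FALSE]
  cross_k <- cross_k[ord]
  # snap to nearest ring point
  jref <- integer(length(cross_k))
  for (i in seq_along(cross_k)) {
    ring <- grid$rings[[cross_k[i]]]
    d2 <- (ring$points[, 1] - pts[i, 1])^2 + (ring$points[, 2] - pts[i, 2])^2
    jref[i] <- which.min(d2)
  }
  refs <- cbind(k = cross_k, j = jref)
  # collapse consecutive duplicates (cyclic)
  keep <- rep(TRUE, nrow(refs))
  for (i in seq_len(nrow(refs))) {
    nxt <- if (i == nrow(refs)) 1L else i + 1L
    if (refs[i, 1] == refs[nxt, 1] && refs[i, 2] == refs[nxt, 2])
      keep[nxt] <- FALSE
  }
  refs <- refs[keep, , drop = FALSE]
  ustar <- ustar[keep]
  # a contour segment running shallowly between planes (tangent dips and
  # near-horizontal boundary stretches) links crossings that are far apart
  # on the surface, which would leave a long straight chord through the
  # vessel interior; such segments are re-traced by snapping the in-between
  # spline arc to the nearest points of the two incident rings
  expanded_refs <- list(); expanded_u <- list()
  nref0 <- nrow(refs)
  for (i in seq_len(nref0)) {
    nxt <- if (i == nref0) 1L else i + 1L
    expanded_refs[[length(expanded_refs) + 1L]] <- refs[i, ]
    expanded_u[[length(expanded_u) + 1L]] <- ustar[i]
    k1 <- refs[i, 1]; k2 <- refs[nxt, 1]
    ring <- grid$rings[[k1]]
    n_k <- ring$n_k
    ring_sp <- ring$circumference / n_k
    plane_sp <- if (length(zs) > 1L) zs[2] - zs[1] else ring_sp
    # circumferential target on ring k1: the next reference itself (same
    # ring) or the ring-k1 point underneath it (adjacent ring)
    j_tgt <- if (k2 == k1) refs[nxt, 2]
    else round((refs[nxt, 2] - 1) / grid$rings[[k2]]$n_k * n_k) %% n_k + 1L
    dj_fwd <- (j_tgt - refs[i, 2]) %% n_k
    sep <- min(dj_fwd, n_k - dj_fwd) * ring_sp
    if (sep <= 3 * max(ring_sp, plane_sp)) next
    # walk along ring k1 on the side the spline actually travels
    u1 <- ustar[i]
    u2 <- if (nxt == 1L) ustar[1L] + 1 else ustar[nxt]
    pmid <- predict(spline, ((u1 + u2) / 2) %% 1)
    jmid <- which.min((ring$points[, 1] - pmid[1])^2 +
                        (ring$points[, 2] - pmid[2])^2)
    on_fwd <- ((jmid - refs[i, 2]) %% n_k) <= dj_fwd
    step <- if (on_fwd) 1L else -1L
    npts <- (if (on_fwd) dj_fwd else (n_k - dj_fwd) %% n_k) - 1L +
      (if (k2 == k1) 0L else 1L)   # include the under-target point itself
    if (npts < 1L) next
    js <- ((refs[i, 2] - 1L + step * seq_len(npts)) %% n_k) + 1L
    for (m in seq_along(js)) {
      expanded_refs[[length(expanded_refs) + 1L]] <- c(k1, js[m])
      expanded_u[[length(expanded_u) + 1L]] <-
        (u1 + (u2 - u1) * m / (npts + 1L)) %% 1
    }
  }
  refs <- do.call(rbind, expanded_refs)
  colnames(refs) <- c("k", "j")
  ustar <- unlist(expanded_u)
  # re-collapse consecutive duplicates across insertion boundaries
  keep <- rep(TRUE, nrow(refs))
  for (i in seq_len(nrow(refs))) {
    nxt <- if (i == nrow(refs)) 1L else i + 1L
    if (refs[i, 1] == refs[nxt, 1] && refs[i, 2] == refs[nxt, 2])
      keep[nxt] <- FALSE
  }
  refs <- refs[keep, , drop = FALSE]
  ustar <- ustar[keep]
  if (nrow(refs) < 3L)
    stop(sprintf("cell %s: fewer than 3 distinct projected points",
                 spline$cell_id), call. = FALSE)
  dk <- abs(diff(c(refs[, 1], refs[1, 1])))
  if (any(dk > 1L))
    stop(sprintf("cell %s: contour crossing skips a plane (spline too coarse for the plane spacing)",
                 spline$cell_id), call. = FALSE)
  pts3 <- t(vapply(seq_len(nrow(refs)), function(i)
    grid$rings[[refs[i, 1]]]$points[refs[i, 2], ], numeric(3)))
  structure(list(cell_id = spline$cell_id, refs = refs, points = pts3,
                 u = ustar),
            class = "projected_contour")
}

#' @export
print.projected_contour <- function(x, ...) {
  cat(sprintf("Projected contour (cell %s): %d grid points on rings %d..%d\n",
              x$cell_id, nrow(x$refs), min(x$refs[, 1]), max(x$refs[, 1])))
  invisible(x)
}

# Lifted circumferential coordinate (in turns) of each contour reference,
# unwrapped so consecutive steps are the shorter way around.
lift_t <- function(refs, grid) {
  t0 <- vapply(seq_len(nrow(refs)), function(i)
    (refs[i, 2] - 1) / grid$rings[[refs[i, 1]]]$n_k, numeric(1))
  tl <- numeric(length(t0))
  tl[1] <- t0[1]
  for (i in seq_along(t0)[-1]) {
    d <- (t0[i] - t0[i - 1]) %% 1
    if (d > 0.5) d <- d - 1
    tl[i] <- tl[i - 1] + d
  }
  closing <- (t0[1] - t0[length(t0)]) %% 1
  if (closing > 0.5) closing <- closing - 1
  list(t = tl, winding = round(tl[length(tl)] + closing - tl[1]))
}

# Greedy strip triangulation between two ordered 3D paths. Returns a matrix
# of local index triples: positive = P index, negative = Q index.
stitch_paths <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  tris <- matrix(0L, n + m - 2L, 3L)
  i <- 1L; j <- 1L; tcount <- 0L
  while (i < n || j < m) {
    tcount <- tcount + 1L
    if (i == n) {
      tris[tcount, ] <- c(i, -j, -(j + 1L)); j <- j + 1L
    } else if (j == m) {
      tris[tcount, ] <- c(i, i + 1L, -j); i <- i + 1L
    } else {
      d_advP <- sum((P[i + 1L, ] - Q[j, ])^2)
      d_advQ <- sum((Q[j + 1L, ] - P[i, ])^2)
      if (d_advP <= d_advQ) {
        tris[tcount, ] <- c(i, i + 1L, -j); i <- i + 1L
      } else {
        tris[tcount, ] <- c(i, -j, -(j + 1L)); j <- j + 1L
      }
    }
  }
  tris
}

#' Triangulate a cell surface within its projected contour
#'
#' Builds a per-cell triangle mesh between each pair of neighbouring
#' cross-sections: within-cell ring paths connecting the contour's bridging
#' edges are identified in an unrolled (circumferential position, ring)
#' chart — the cell side of the ambiguous contour orientation is extracted
#' by parity tests against the contour polygon in that chart — and
#' neighbouring paths are joined by a strip of triangles, each using two
#' adjacent points on one ring and one on the other, interior points linking
#' to their nearest neighbour on the opposite ring. All edges of the
#' projected contour are edges of the triangulation; this is verified and a
#' mismatch (deeply non-convex cell region) raises an error.
#'
#' @param proj a [project_contour_to_grid()] result.
#' @param grid the [build_grid()] result the contour was projected onto.
#' @return Object of class `cell_mesh`: `cell_id`, `vertices` (V x 3),
#'   `keys` (V x 2 ring/point indices), `triangles` (T x 3 vertex indices),
#'   `boundary_edges` (E x 2), `winding`.
#' @export
triangulate_cell <- function(proj, grid) {
  refs <- proj$refs
  nref <- nrow(refs)
  lift <- lift_t(refs, grid)
  key <- paste(refs[, 1], refs[, 2])
  if (anyDuplicated(key))
    stop(sprintf("cell %s: contour revisits a grid point (pinched contour)",
                 proj$cell_id), call. = FALSE)
  kmin <- min(refs[, 1]); kmax <- max(refs[, 1])
  if (lift$winding == 0) {
    mesh <- triangulate_disc_cell(proj, grid, lift, kmin, kmax)
  } else if (abs(lift$winding) == 1) {
    mesh <- triangulate_band_cell(proj, grid, kmin, kmax)
  } else {
    stop(sprintf("cell %s: contour winds %d times around the vessel",
                 proj$cell_id, lift$winding), call. = FALSE)
  }
  mesh$cell_id <- proj$cell_id
  class(mesh) <- "cell_mesh"
  if (lift$winding == 0) check_mesh_boundary(mesh, proj)
  mesh
}

triangulate_disc_cell <- function(proj, grid, lift, kmin, kmax) {
  refs <- proj$refs
  nref <- nrow(refs)
  tl <- lift$t
  poly <- cbind(tl, refs[, 1])
  nxt <- c(2:nref, 1L)
  prv <- c(nref, 1:(nref - 1L))

  # per ring: crossing positions of up- and down-bridges (for parity tests)
  up_x <- vector("list", kmax)
  dn_x <- vector("list", kmax)
  for (i in seq_len(nref)) {
    k <- refs[i, 1]
    for (nb in c(nxt[i], prv[i])) {
      if (refs[nb, 1] == k + 1L) up_x[[k]] <- c(up_x[[k]], tl[i])
      if (refs[nb, 1] == k - 1L) dn_x[[k]] <- c(dn_x[[k]], tl[i])
    }
  }
  parity_above <- function(k, x) {
    cr <- up_x[[k]]
    (sum(cr < x) %% 2L) == 1L
  }
  parity_below <- function(k, x) {
    cr <- dn_x[[k]]
    (sum(cr < x) %% 2L) == 1L
  }

  # in-cell members per ring and band side
  ring_members <- function(k, side) {
    # side "up": members of the lower path of band (k, k+1)
    # side "down": members of the upper path of band (k-1, k)
    out_t <- numeric(0); out_j <- integer(0)
    for (i in which(refs[, 1] == k)) {
      use <- FALSE
      for (nb in c(nxt[i], prv[i])) {
        if (side == "up" && refs[nb, 1] == k + 1L) use <- TRUE
        if (side == "down" && refs[nb, 1] == k - 1L) use <- TRUE
        if (refs[nb, 1] == k) { # chord: belongs to the band on the cell side
          xm <- (tl[i] + tl[nb]) / 2
          if (side == "up" && parity_above(k, xm)) use <- TRUE
          if (side == "down" && parity_below(k, xm)) use <- TRUE
        }
      }
      if (use) { out_t <- c(out_t, tl[i]); out_j <- c(out_j, refs[i, 2]) }
    }
    # strictly interior ring points (inside above and below)
    n_k <- grid$rings[[k]]$n_k
    trange <- range(tl)
    ref_j_on_k <- refs[refs[, 1] == k, 2]
    for (j in seq_len(n_k)) {
      if (j %in% ref_j_on_k) next
      t0 <- (j - 1) / n_k
      for (m in floor(trange[1] - t0):ceiling(trange[2] - t0)) {
        x <- t0 + m
        if (x < trange[1] || x > trange[2]) next
        if (parity_above(k, x) && parity_below(k, x)) {
          out_t <- c(out_t, x); out_j <- c(out_j, j)
        }
      }
    }
    ord <- order(out_t)
    list(t = out_t[ord], j = out_j[ord])
  }

  verts <- list(); vkeys <- character(0)
  vindex <- function(k, j) {
    key <- paste(k, j)
    pos <- match(key, vkeys)
    if (!is.na(pos)) return(pos)
    verts[[length(verts) + 1L]] <<- c(grid$rings[[k]]$points[j, ], k, j)
    vkeys[length(vkeys) + 1L] <<- key
    length(verts)
  }
  tris <- list()
  for (k in kmin:(kmax - 1L)) {
    P <- ring_members(k, "up")
    Q <- ring_members(k + 1L, "down")
    if (length(P$j) == 0L || length(Q$j) == 0L)
      stop(sprintf("cell %s: empty ring path between planes %d and %d",
                   proj$cell_id, k, k + 1L), call. = FALSE)
    Pidx <- vapply(P$j, function(j) vindex(k, j), integer(1))
    Qidx <- vapply(Q$j, function(j) vindex(k + 1L, j), integer(1))
    Pm <- do.call(rbind, verts[Pidx])[, 1:3, drop = FALSE]
    Qm <- do.call(rbind, verts[Qidx])[, 1:3, drop = FALSE]
    if (length(Pidx) == 1L && length(Qidx) == 1L) next
    st <- stitch_paths(matrix(Pm, ncol = 3), matrix(Qm, ncol = 3))
    for (r in seq_len(nrow(st))) {
      tri <- st[r, ]
      tris[[length(tris) + 1L]] <-
        ifelse(tri > 0, Pidx[abs(tri)], Qidx[abs(tri)])
    }
  }
  finish_mesh(verts, tris)
}

triangulate_band_cell <- function(proj, grid, kmin, kmax) {
  verts <- list()
  tris <- list()
  offset <- 0L
  ring_sizes <- integer(0)
  for (k in kmin:kmax) {
    ring <- grid$rings[[k]]
    for (j in seq_len(ring$n_k))
      verts[[length(verts) + 1L]] <- c(ring$points[j, ], k, j)
    ring_sizes <- c(ring_sizes, ring$n_k)
  }
  start <- cumsum(c(0L, ring_sizes[-length(ring_sizes)]))
  for (b in seq_len(kmax - kmin)) {
    P <- do.call(rbind, verts[start[b] + seq_len(ring_sizes[b])])[, 1:3]
    Q <- do.call(rbind, verts[start[b + 1] + seq_len(ring_sizes[b + 1])])[, 1:3]
    st <- stitch_rings(P, Q)
    for (r in seq_len(nrow(st))) {
      tri <- st[r, ]
      tris[[length(tris) + 1L]] <- ifelse(tri > 0, start[b] + abs(tri),
                                          start[b + 1] + abs(tri))
    }
  }
  m <- finish_mesh(verts, tris)
  m$winding <- 1L
  m
}

# Cyclic greedy stitch between two full rings (closed paths).
stitch_rings <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  j0 <- which.min(colSums((t(Q) - P[1, ])^2))
  Pw <- rbind(P, P[1, , drop = FALSE])
  Qw <- rbind(Q[j0:m, , drop = FALSE], Q[seq_len(j0), , drop = FALSE])
  st <- stitch_paths(Pw, Qw)
  # remap wrapped indices back to ring indices
  st_p <- ifelse(st > 0, ((abs(st) - 1L) %% n) + 1L, 0L)
  st_q <- ifelse(st < 0, ((abs(st) + j0 - 2L) %% m) + 1L, 0L)
  out <- matrix(0L, nrow(st), 3L)
  out[st > 0] <- st_p[st > 0]
  out[st < 0] <- -st_q[st < 0]
  out
}

finish_mesh <- function(verts, tris) {
  V <- do.call(rbind, verts)
  triangles <- do.call(rbind, tris)
  storage.mode(triangles) <- "integer"
  # drop exactly degenerate triangles (repeated vertex indices)
  ok <- triangles[, 1] != triangles[, 2] & triangles[, 2] != triangles[, 3] &
    triangles[, 1] != triangles[, 3]
  triangles <- triangles[ok, , drop = FALSE]
  edges <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(ekey)
  bkeys <- names(cnt)[cnt == 1L]
  bidx <- match(bkeys, ekey)
  boundary <- edges[bidx, , drop = FALSE]
  list(vertices = V[, 1:3, drop = FALSE], keys = V[, 4:5, drop = FALSE],
       triangles = triangles, boundary_edges = boundary, winding = 0L)
}

check_mesh_boundary <- function(mesh, proj) {
  refs <- proj$refs
  n <- nrow(refs)
  nxt <- c(2:n, 1L)
  vk <- paste(mesh$keys[, 1], mesh$keys[, 2])
  a <- match(paste(refs[, 1], refs[, 2]), vk)
  b <- a[nxt]
  contour_edges <- sort(paste(pmin(a, b), pmax(a, b)))
  bound <- mesh$boundary_edges
  bound_edges <- sort(paste(pmin(bound[, 1], bound[, 2]),
                            pmax(bound[, 1], bound[, 2])))
  if (length(contour_edges) != length(bound_edges) ||
      any(contour_edges != bound_edges))
    stop(sprintf("cell %s: mesh boundary does not match the projected contour (non-convex cell region)",
                 proj$cell_id), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("Cell mesh %s: %d vertices, %d triangles, area %.2f um^2\n",
              x$cell_id, nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Surface area of a triangle mesh
#'
#' @param mesh a `cell_mesh` (or any list with `vertices` and `triangles`).
#' @return Total triangle area (um^2).
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh$vertices, mesh$triangles))
}

#' Triangulated full vessel surface
#'
#' Joins all consecutive grid rings into one triangle mesh (the reference
#' lateral surface used for area bookkeeping, slicing and export).
#'
#' @param grid a [build_grid()] result.
#' @return A mesh list (`vertices`, `keys`, `triangles`, `boundary_edges`).
#' @export
grid_mesh <- function(grid) {
  proj_dummy <- list(cell_id = "grid", refs = cbind(k = 1L, j = 1L))
  mesh <- triangulate_band_cell(proj_dummy, grid, 1L, length(grid$rings))
  mesh$cell_id <- "grid"
  class(mesh) <- "cell_mesh"
  mesh
}
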