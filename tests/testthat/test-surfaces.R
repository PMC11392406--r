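# Analytic circular-cylinder grid for projection/triangulation oracles.
cyl_grid <- function(radius = 5, zmax = 10, dz = 1, n_cross_rel = 2) {
  z <- seq(0, zmax, by = dz)
  theta <- t(vapply(z, cylinder_theta(radius), numeric(7)))
  build_grid(theta, z, n_cross_rel)
}

# Periodic spline through a rectangular patch outline on the cylinder
# surface: angular range [a1, a2], axial range [z1, z2].
patch_spline <- function(radius, a1, a2, z1, z2, n_per_edge = 30) {
  s1 <- seq(a1, a2, length.out = n_per_edge)
  s2 <- seq(z1, z2, length.out = n_per_edge)
  pts <- rbind(cbind(radius * cos(s1), radius * sin(s1), z1),
               cbind(radius * cos(a2), radius * sin(a2), s2[-1]),
               cbind(radius * cos(rev(s1)), radius * sin(rev(s1)), z2)[-1, ],
               cbind(radius * cos(a1), radius * sin(a1), rev(s2))[-c(1, n_per_edge), ])
  keep <- c(TRUE, rowSums((pts[-1, ] - pts[-nrow(pts), ])^2) > 1e-18)
  fit_periodic_spline(vessel_contour("patch", pts[keep, ]), eps_spline = 1e-6)
}

test_that("contour projection snaps plane crossings to boundary ring points", {
  grid <- cyl_grid()
  sp <- patch_spline(5, 0.3, 1.8, 2.1, 7.9)
  proj <- project_contour_to_grid(sp, grid)
  # uses only planes 4..9 (z = 3..8) and ring points on the patch sides
  expect_equal(sort(unique(proj$refs[, "k"])), 4:8)
  ring <- grid$rings[[4]]
  ang <- atan2(proj$points[, 2], proj$points[, 1])
  expect_true(all(ang > 0.3 - 0.2 & ang < 1.8 + 0.2))
  # all projected points lie on the cylinder within the ring chord error
  expect_lt(max(abs(sqrt(rowSums(proj$points[, 1:2]^2)) - 5)), 0.01)
  # Hausdorff-type distance to the analytic boundary below grid resolution
  d <- contour_distance(proj$points, predict(sp, seq(0, 1, length.out = 400)))
  expect_lt(d, 2 * (0.5 + 1))   # ring spacing + plane spacing bound
})

test_that("projection fails cleanly between planes or with too few crossings", {
  grid <- cyl_grid()
  sp <- patch_spline(5, 0.3, 1.8, 2.1, 2.9)  # entirely between two planes
  expect_error(project_contour_to_grid(sp, grid), "planes|crossings")
})

test_that("strip triangulation count and boundary-edge identity hold", {
  grid <- cyl_grid()
  sp <- patch_spline(5, 0.4, 2.6, 3.6, 5.4)  # spans exactly planes 5 and 6
  proj <- project_contour_to_grid(sp, grid)
  expect_setequal(unique(proj$refs[, "k"]), c(5L, 6L))
  mesh <- triangulate_cell(proj, grid)
  n1 <- sum(mesh$keys[, 1] == 5); n2 <- sum(mesh$keys[, 1] == 6)
  expect_equal(nrow(mesh$triangles), n1 + n2 - 2L)
  # boundary edges == projected contour edges (multiset), verified
  # independently of the builder's own check
  vk <- paste(mesh$keys[, 1], mesh$keys[, 2])
  refk <- paste(proj$refs[, 1], proj$refs[, 2])
  idx <- match(refk, vk)
  nn <- length(idx)
  ce <- sort(paste(pmin(idx, idx[c(2:nn, 1)]), pmax(idx, idx[c(2:nn, 1)])))
  be <- sort(paste(pmin(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2]),
                   pmax(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2])))
  expect_identical(be, ce)
  expect_true(all(lumenfit:::triangle_areas(mesh$vertices,
                                            mesh$triangles) > 1e-12))
})

test_that("a larger patch mesh approximates its analytic lateral area", {
  grid <- cyl_grid(radius = 5, zmax = 10, dz = 0.5, n_cross_rel = 4)
  # narrow patch so boundary chords are close to the surface arcs; the
  # mesh covers the axial span between the extreme crossed planes
  sp <- patch_spline(5, 0.2, 0.6, 0.95, 9.05)
  proj <- project_contour_to_grid(sp, grid)
  mesh <- triangulate_cell(proj, grid)
  analytic <- 5 * 0.4 * 8   # r * dtheta * (crossed-plane span)
  expect_close(mesh_area(mesh) / analytic, 1, 0.05)
})

test_that("full vessel grid mesh area matches the analytic cylinder area", {
  grid <- cyl_grid(radius = 5, zmax = 10, dz = 0.5, n_cross_rel = 4)
  gm <- grid_mesh(grid)
  expect_close(mesh_area(gm) / (2 * pi * 5 * 10), 1, 0.01)
})

test_that("cells of a full tessellation partition the grid surface area", {
  tp <- truth_pipeline_clean()
  total_cells <- sum(vapply(tp$meshes, mesh_area, numeric(1)))
  # compare over the z-range actually covered by cells (the grid extends to
  # the annotation extremes)
  gm <- grid_mesh(tp$grid)
  expect_close(total_cells / mesh_area(gm), 1, 0.01)
  # watertightness: every cell's boundary multiset equals its contour edges
  for (id in names(tp$meshes)) {
    mesh <- tp$meshes[[id]]; proj <- tp$projs[[id]]
    vk <- paste(mesh$keys[, 1], mesh$keys[, 2])
    idx <- match(paste(proj$refs[, 1], proj$refs[, 2]), vk)
    nn <- length(idx)
    ce <- sort(paste(pmin(idx, idx[c(2:nn, 1)]), pmax(idx, idx[c(2:nn, 1)])))
    be <- sort(paste(pmin(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2]),
                     pmax(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2])))
    expect_identical(be, ce)
  }
})
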