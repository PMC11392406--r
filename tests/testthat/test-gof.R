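test_that("point-to-contour distance is the clamped segment minimum", {
  seg <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_equal(point_to_contour_distance(c(0, 1, 0), seg), 1)
  expect_equal(point_to_contour_distance(c(3, 0, 0), seg), 2)  # clamped end
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(point_to_contour_distance(c(0.5, 0, 0), sq), 0)  # on an edge
  # brute force over densified points (slightly above: densification only
  # approaches segments from outside)
  set.seed(1)
  p <- matrix(runif(30, -2, 3), ncol = 3)
  dense <- densify <- lumenfit:::densify_contour(sq, 1e-3)
  d_brute <- apply(p, 1, function(q)
    sqrt(min(colSums((t(dense) - q)^2))))
  d_pkg <- point_to_contour_distance(p, sq)
  expect_true(all(d_pkg <= d_brute + 1e-12))
  expect_lt(max(abs(d_pkg - d_brute)), 1e-3)
})

test_that("symmetric contour distance: identity, symmetry, offset oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(contour_distance(sq, sq), 0)
  sq2 <- sq; sq2[, 1] <- sq2[, 1] + 0.1
  d <- contour_distance(sq, sq2)
  expect_identical(d, contour_distance(sq2, sq))
  # dense brute-force oracle
  A <- lumenfit:::densify_contour(sq, 0.005)
  B <- lumenfit:::densify_contour(sq2, 0.005)
  dAB <- mean(apply(A, 1, function(q) sqrt(min(colSums((t(B) - q)^2)))))
  dBA <- mean(apply(B, 1, function(q) sqrt(min(colSums((t(A) - q)^2)))))
  expect_close(d, max(dAB, dBA), 1e-3)
  expect_error(contour_distance(sq[1:2, ], sq), "degenerate")
})

test_that("projection distance rises with annotation noise (rank check)", {
  tp <- truth_pipeline_clean()
  grid <- tp$grid
  meds <- vapply(c(0, 0.25, 0.5), function(ns) {
    sim <- simulate_vessel(tube_spec(length = 40, n_cells = 10, noise_sd = ns,
                                     seed = 5, transform = rigid_transform()))
    ctl <- vessel_control(M_rel = 2, n_cross_rel = 4, eps_spline = 0.005)
    prep <- preprocess_contours(sim$dataset, ctl)
    ds <- vapply(names(prep$splines), function(id) {
      proj <- tryCatch(project_contour_to_grid(prep$splines[[id]], grid),
                       error = function(e) NULL)
      if (is.null(proj)) return(NA_real_)
      projection_distance(sim$dataset$contours[[id]], proj)
    }, numeric(1))
    stats::median(ds, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  # noise-free: below the grid resolution bound
  expect_lt(meds[1], 2 * (0.25 + 0.5))
})

test_that("mesh slicing reproduces analytic cylinder cross-sections", {
  z <- seq(0, 10, by = 0.5)
  grid <- build_grid(t(vapply(z, cylinder_theta(5), numeric(7))), z, 4)
  gm <- grid_mesh(grid)
  # transverse plane -> circle radius 5
  sl <- slice_mesh(gm, list(point = c(0, 0, 5.25), normal = c(0, 0, 1)))
  r <- sqrt(rowSums(sl$polygon_2d^2))
  expect_close(mean(r), 5, 0.05)
  expect_close(polygon_area(sl$polygon_2d), pi * 25, 0.01 * pi * 25)
  # oblique plane -> ellipse with axes r and r / cos(tilt)
  tilt <- 0.3
  sl2 <- slice_mesh(gm, list(point = c(0, 0, 5), normal = c(0, sin(tilt), cos(tilt))))
  a2 <- polygon_area(sl2$polygon_2d)
  expect_close(a2, pi * 5 * 5 / cos(tilt), 0.01 * a2)
  xr <- diff(range(sl2$polygon_2d[, 1]))
  yr <- diff(range(sl2$polygon_2d[, 2]))
  expect_close(xr, 10, 0.1)
  expect_close(yr, 10 / cos(tilt), 0.1)
  # y' axis aligned with the dorsal direction's in-plane projection
  top <- sl$polygon_3d[which.max(sl$polygon_2d[, 2]), ]
  expect_gt(top[2], 4.9)
  # plane missing the surface
  expect_error(slice_mesh(gm, list(point = c(0, 0, 50), normal = c(0, 0, 1))),
               "transversally|loop")
})

test_that("slice at a grid plane reproduces that plane's ring", {
  z <- seq(0, 10, by = 1)
  grid <- build_grid(t(vapply(z, cylinder_theta(5), numeric(7))), z, 2)
  gm <- grid_mesh(grid)
  sl <- slice_mesh(gm, list(point = c(0, 0, 4 + 1e-6), normal = c(0, 0, 1)))
  ring <- grid$rings[[5]]$points
  d <- contour_distance(sl$polygon_3d, ring)
  expect_lt(d, 0.5)   # within the ring spacing
})

test_that("slice comparison returns analytic shape and area deviations", {
  u <- seq(0, 2 * pi, length.out = 361)[-361]
  c1 <- cbind(1.1 * cos(u), 1.1 * sin(u))
  c0 <- cbind(cos(u), sin(u))
  cmp <- compare_slices(c1, c0)
  expect_close(cmp$dev_cross, 0.21, 1e-3)
  expect_close(cmp$dev_rel_area, (1.21 * pi - pi) / (1.21 * pi), 1e-3)
  same <- compare_slices(c0, c0)
  expect_identical(same$dev_cross, 0)
  expect_identical(same$dev_rel_area, 0)
})

test_that("angiogram-style slice validation recovers near-zero deviations on the truth surface", {
  sim <- sim_clean()
  truth <- sim$truth
  gm <- grid_mesh(truth$grid)
  # build synthetic angiogram slices directly from the truth surface
  slices <- lapply(c(9.7, 20.2, 31.4), function(zk) {
    th <- lumenfit:::as_shape_params(sim$spec$theta_fn(zk))
    eq <- shape_equidistant(th, n_k = 40)
    cbind(eq$points, zk)
  })
  out <- validate_against_slices(gm, slices)
  expect_equal(nrow(out), 3L)
  expect_lt(max(out$dev_cross), 0.02)
  expect_lt(max(abs(out$dev_rel_area)), 0.02)
})
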