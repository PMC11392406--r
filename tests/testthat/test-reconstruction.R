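test_that("plane planning spans the z-range with floor(M_rel * extent) planes", {
  pts <- cbind(0, 0, c(0, 100))
  z <- plan_planes(pts, 10)
  expect_length(z, 1000L)
  expect_equal(range(z), c(0, 100))
  expect_lt(diff(range(diff(z))), 1e-9)
  z2 <- plan_planes(cbind(0, 0, c(0, 1)), 2)
  expect_equal(z2, c(0, 1))
  expect_error(plan_planes(cbind(0, 0, c(0, 0.4)), 2), "resolution")
  expect_error(plan_planes(cbind(0, 0, c(1, 1)), 2), "distinct")
})

test_that("truncated Gaussian weights follow the closed form", {
  expect_identical(gauss_weight(0, 1), 1)
  expect_equal(gauss_weight(1, 1), exp(-0.5))
  expect_equal(gauss_weight(3, 1.5, 2), exp(-2))          # at the cut
  expect_identical(gauss_weight(3 + 1e-9, 1.5, 2), 0)     # just beyond
  expect_equal(gauss_weight(c(-2, 0, 2), 2, 2), c(exp(-0.5), 1, exp(-0.5)))
})

test_that("adaptive width is the minimal omega giving n_oct points per octant", {
  # 8 octant directions, points stacked at controlled z-distances
  ang <- (0:7) * pi / 4 + pi / 8
  mk <- function(dz_per_oct) {
    do.call(rbind, lapply(1:8, function(o)
      cbind(cos(ang[o]) * 5, sin(ang[o]) * 5, dz_per_oct[[o]])))
  }
  # one octant's n_oct-th nearest at |dz| = 4, others nearer -> omega = 2
  dz <- rep(list(c(0, 0.1, 0.2)), 8)
  dz[[3]] <- c(0.1, 0.5, 4)
  pts <- mk(dz)
  om <- adaptive_width(pts, z_k = 0, n_oct = 3, Z_omega = 2)
  expect_equal(om, 2)
  # minimality: 1% smaller omega loses an octant
  w <- gauss_weight(pts[, 3], 0.99 * om, 2)
  oct <- lumenfit:::octant_index(pts[, 1:2])
  expect_true(any(tapply(w > 0, oct, sum) < 3))
  # all points at z_k -> clamped floor
  pts0 <- mk(rep(list(c(0, 0, 0)), 8))
  expect_equal(adaptive_width(pts0, 0, 3, 2), 1e-6)
  # an octant lacking n_oct points errors with its number
  expect_error(adaptive_width(pts[-(7:9), ], 0, 3, 2), "octant 3")
})

test_that("octant boundaries are assigned counter-clockwise", {
  xy <- rbind(c(1, 0), c(1, 1) / sqrt(2), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(lumenfit:::octant_index(xy), c(1L, 2L, 3L, 5L, 7L))
})

test_that("cross-section fitting recovers a known shape and respects the constraint", {
  truth <- shape_params(0.3, -0.2, 9.5, 10.5, 10, 0.8, 1.1)
  mean_shape <- shape_params(0, 0, 9, 11, 10, 0.85, 1.0)
  eq <- shape_equidistant(truth, 4)
  pts <- cbind(eq$points, z = 0)
  ctl <- vessel_control()
  fit <- fit_cross_section(pts, 0, 1, mean_shape, lambda = 0.2, ctl)
  expect_lt(dev_cross(fit$theta, truth), 0.01)
  expect_lte(fit$dev, 0.2 + 1e-6)
  # lambda = 0 returns the mean shape
  fit0 <- fit_cross_section(pts, 0, 1, mean_shape, lambda = 0, ctl)
  expect_equal(as.numeric(fit0$theta), as.numeric(mean_shape))
  # noisy points: fitted objective no worse than the initialisation
  set.seed(4)
  ptsn <- pts + cbind(matrix(rnorm(2 * nrow(pts), 0, 0.25), ncol = 2), 0)
  fitn <- fit_cross_section(ptsn, 0, 1, mean_shape, lambda = 0.2, ctl)
  w <- gauss_weight(ptsn[, 3], 1, ctl$Z_omega)
  obj0 <- sum(w * shape_project(mean_shape, ptsn[, 1:2])$distance)
  expect_lte(fitn$objective, obj0)
})

test_that("constraint projection blends to feasibility when the data pull beyond lambda", {
  truth <- shape_params(0, 0, 13, 13, 13, 1, 1)   # 30%+ away from the mean
  mean_shape <- shape_params(0, 0, 10, 10, 10, 1, 1)
  eq <- shape_equidistant(truth, 4)
  fit <- fit_cross_section(cbind(eq$points, z = 0), 0, 1, mean_shape,
                           lambda = 0.1, vessel_control())
  expect_lte(fit$dev, 0.1 + 1e-6)
  expect_gt(fit$dev, 0.05)   # pulled towards the bound, not stuck at 0
})

test_that("parameter smoothing is a renormalised truncated Gaussian filter", {
  z <- seq(0, 50, by = 0.5)
  M <- length(z)
  const <- matrix(rep(c(0, 0, 9, 11, 10, 0.8, 1), each = M), nrow = M)
  expect_equal(smooth_shape_params(const, z, 5, 2), const)
  # impulse response equals the normalised truncated kernel
  imp <- matrix(0, M, 7); imp[1, 3] <- 1
  sm <- smooth_shape_params(imp, z, 1, 2)
  kern <- function(o) exp(-(o * 0.5)^2 / 2)
  expected <- vapply(1:5, function(k) {
    offs <- max(1 - k, -4):4          # window available at plane k
    kern(1 - k) / sum(kern(offs))
  }, numeric(1))
  expect_equal(sm[1:5, 3], expected, tolerance = 1e-12)
  # semigroup: twice with sigma ~ once with sigma * sqrt(2) (interior)
  set.seed(8)
  ran <- matrix(rnorm(7 * M), M, 7)
  twice <- smooth_shape_params(smooth_shape_params(ran, z, 1, 4), z, 1, 4)
  once <- smooth_shape_params(ran, z, sqrt(2), 4)
  interior <- 20:(M - 20)
  expect_lt(max(abs(twice[interior, ] - once[interior, ])) /
              stats::sd(ran), 0.01)
  # sigma = 0 disables smoothing
  expect_equal(smooth_shape_params(ran, z, 0, 2), ran)
})

test_that("grid construction yields simple, ordered, sufficiently dense rings", {
  z <- seq(0, 10, by = 1)
  theta <- t(vapply(z, cylinder_theta(5), numeric(7)))
  grid <- build_grid(theta, z, 2)
  expect_s3_class(grid, "vessel_grid")
  expect_length(grid$rings, 11L)
  expect_true(all(diff(vapply(grid$rings, function(r) r$z, numeric(1))) > 0))
  for (r in grid$rings[c(1, 6)]) {
    expect_gte(r$n_k, 8L)
    expect_equal(r$n_k, floor(2 * 2 * pi * 5))
    expect_lt(max(abs(sqrt(rowSums(r$points[, 1:2]^2)) - 5)), 1e-3)
  }
})
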