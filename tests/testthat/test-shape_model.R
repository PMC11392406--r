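test_that("shape evaluation hits the analytic landmarks and joins continuously", {
  th <- shape_params(0, 0, 1, 1, 1, 1, 1)
  expect_equal(as.numeric(shape_evaluate(th, pi / 2)), c(0, 1), tolerance = 1e-12)
  th2 <- shape_params(0, 0, 1, 2, 1, 1, 1)
  expect_equal(as.numeric(shape_evaluate(th2, 3 * pi / 2)), c(0, -2),
               tolerance = 1e-12)
  # alpha = beta = 1 reduces to an ellipse on the dorsal half
  the <- shape_params(0.5, -0.25, 2, 1.5, 1, 1, 1)
  u <- seq(0, pi, length.out = 100)
  p <- shape_evaluate(the, u)
  expect_lt(max(abs((p[, 1] - 0.5)^2 / 1^2 + (p[, 2] + 0.25)^2 / 2^2 - 1)),
            1e-12)
  # continuity at the joins and symmetry about x = m_x
  for (th3 in list(shape_params(1, 2, 3, 2, 2.5, 0.4, 1.7),
                   shape_params(0, 0, 1, 1, 1, 0.05, 2))) {
    # Hoelder continuity at the joins: the gap shrinks to 0 as eps -> 0
    gap <- vapply(c(1e-3, 1e-6, 1e-12), function(eps)
      max(abs(shape_evaluate(th3, pi - eps) - shape_evaluate(th3, pi + eps)),
          abs(shape_evaluate(th3, eps) - shape_evaluate(th3, 2 * pi - eps))),
      numeric(1))
    expect_true(all(diff(gap) < 0))
    amax <- max(th3[c("a", "b", "c")])
    emin <- min(th3[c("alpha", "beta")])
    expect_lt(gap[3], 4 * amax * (1e-12)^emin + 1e-9)
    u <- seq(0.1, pi - 0.1, length.out = 33)
    pd <- shape_evaluate(th3, u)
    pm <- shape_evaluate(th3, pi - u)
    expect_equal(pd[, 1] - th3[["m_x"]], -(pm[, 1] - th3[["m_x"]]),
                 tolerance = 1e-10)
    expect_equal(pd[, 2], pm[, 2], tolerance = 1e-10)
  }
})

test_that("parameter validation rejects degenerate shapes", {
  expect_error(shape_params(a = -1), "positive")
  expect_error(shape_params(alpha = 0.01), "exponents")
  expect_error(shape_params(beta = 2.5), "exponents")
  expect_error(shape_evaluate(shape_params(), 7), "2\\*pi")
})

test_that("circumference matches analytic values and the dense chord table", {
  expect_close(shape_circumference(shape_params()), 2 * pi, 1e-8)
  # ellipse a = 2, c = 1: quadrature vs independent dense chord sum
  the <- shape_params(0, 0, 2, 2, 1, 1, 1)
  u <- seq(0, 2 * pi, length.out = 200001)
  chords <- sum(sqrt(rowSums(diff(cbind(cos(u), 2 * sin(u)))^2)))
  expect_close(shape_circumference(the), chords, 1e-6 * chords)
  # superellipse (singular integrand): quadrature vs the arc table
  ths <- shape_params(0, 0, 1, 1, 1, 0.3, 1.6)
  tab <- lumenfit:::shape_arc_table(ths)
  expect_close(shape_circumference(ths), max(tab$cum), 1e-5)
})

test_that("equidistant sampling is uniform in arc length, first point at u = 0", {
  eq <- shape_equidistant(shape_params(), 10)
  expect_equal(nrow(eq$points), floor(10 * 2 * pi))
  expect_identical(eq$u[1], 0)
  g <- sqrt(rowSums((eq$points[c(2:62, 1), ] - eq$points)^2))
  expect_lt(max(g) / min(g), 1.005)
  # arc-length (not chord) gaps are uniform for flattened shapes too
  ths <- shape_params(0, 0, 8, 10, 9, 0.4, 1.5)
  eq2 <- shape_equidistant(ths, 2)
  tab <- lumenfit:::shape_arc_table(ths)
  arcpos <- stats::approx(tab$u, tab$cum, xout = eq2$u, ties = "ordered")$y
  gaps <- diff(c(arcpos, max(tab$cum)))
  expect_lt(max(gaps) / min(gaps), 1.01)
  expect_error(shape_equidistant(shape_params(), n_k = 5), "resolution")
})

test_that("shape_area recovers analytic areas", {
  expect_close(shape_area(shape_params()), pi, 1e-4)
  expect_close(shape_area(shape_params(0, 0, 2, 2, 1, 1, 1)), 2 * pi, 1e-3)
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_identical(shape_area(sq), 1)
})

test_that("point projection agrees with a dense-sampling oracle", {
  th <- shape_params(0, 0, 1, 1, 1, 1, 1)
  pr <- shape_project(th, c(2, 0))
  expect_close(pr$distance, 1, 1e-4)
  expect_close(max(abs(pr$point - c(1, 0))), 0, 1e-3)
  # random shapes and points vs brute force over 1e5 curve samples
  set.seed(42)
  for (i in 1:5) {
    th <- shape_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, 5, 12),
                       runif(1, 5, 12), runif(1, 5, 12), runif(1, 0.3, 2),
                       runif(1, 0.3, 2))
    dense <- shape_evaluate(th, seq(0, 2 * pi, length.out = 1e5))
    p <- matrix(runif(20, -15, 15), ncol = 2)
    d_pkg <- shape_project(th, p, n_poly = 360)$distance
    d_ora <- apply(p, 1, function(q)
      sqrt(min((dense[, 1] - q[1])^2 + (dense[, 2] - q[2])^2)))
    expect_lt(max(abs(d_pkg - d_ora)), 1e-3)
  }
  # points on the curve project to themselves
  on_curve <- shape_evaluate(th, seq(0.1, 6, length.out = 25))
  expect_lt(max(shape_project(th, on_curve, 360)$distance), 1e-3)
})

test_that("dev_cross matches analytic, Monte-Carlo and shapely oracles", {
  th <- shape_params()
  expect_identical(dev_cross(th, th), 0)
  th2 <- shape_params(0, 0, 1.1, 1.1, 1.1, 1, 1)
  expect_close(dev_cross(th2, th), 0.21, 1e-3)
  # not symmetric: denominator is the reference
  expect_close(dev_cross(th, th2), 0.21 / 1.21, 1e-3)
  # random superellipse pairs vs deterministic dense-grid oracle
  set.seed(7)
  for (i in 1:4) {
    a <- shape_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, 6, 11),
                      runif(1, 6, 11), runif(1, 6, 11), runif(1, 0.3, 1.9),
                      runif(1, 0.3, 1.9))
    b <- shape_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, 6, 11),
                      runif(1, 6, 11), runif(1, 6, 11), runif(1, 0.3, 1.9),
                      runif(1, 0.3, 1.9))
    pa <- shape_polygon(a, 360); pb <- shape_polygon(b, 360)
    got <- dev_cross(a, b)
    sa <- shapely_symdiff_area(pa, pb)
    if (!is.na(sa)) {
      expect_close(got, sa / polygon_area(pb), 5e-3)
    } else {
      # deterministic lattice fallback oracle
      rng <- apply(rbind(pa, pb), 2, range)
      gx <- seq(rng[1, 1], rng[2, 1], length.out = 400)
      gy <- seq(rng[1, 2], rng[2, 2], length.out = 400)
      pts <- cbind(rep(gx, times = 400), rep(gy, each = 400))
      ina <- lumenfit:::.points_in_polygon_cpp(pts, pa)
      inb <- lumenfit:::.points_in_polygon_cpp(pts, pb)
      cell <- diff(gx[1:2]) * diff(gy[1:2])
      expect_close(got, sum(xor(ina, inb)) * cell / polygon_area(pb), 0.02)
    }
  }
})

test_that("circle special case: a = b = c, alpha = beta = 1 gives equal radii", {
  th <- shape_params(2, -3, 5, 5, 5, 1, 1)
  p <- shape_polygon(th, 720)
  r <- sqrt((p[, 1] - 2)^2 + (p[, 2] + 3)^2)
  expect_lt(max(abs(r - 5)), 1e-9)
})
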