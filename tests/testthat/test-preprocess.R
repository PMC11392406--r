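test_that("neighbour enrichment matches a brute-force cylinder oracle", {
  # two near-coincident squares; shared corners offset so they are genuine
  # foreign points (exactly duplicated annotations are skipped by the
  # duplicate guard)
  A <- vessel_contour("1", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  B <- vessel_contour("2", cbind(c(1.01, 2, 2, 1.01), c(0.02, 0, 1, 0.98), 0))
  ds <- contour_dataset(list(A, B), axes_canonical())
  en <- enrich_contours(ds, r = 0.2, dh = 0.1)
  expect_equal(nrow(en$contours[["1"]]$points), 6L)
  expect_equal(nrow(en$contours[["2"]]$points), 6L)
  # inserted points are B's shared-edge corners, between A's (1,0) and (1,1)
  expect_equal(en$contours[["1"]]$points[3:4, 1:2],
               rbind(c(1.01, 0.02), c(1.01, 0.98)), ignore_attr = TRUE)
  # original points remain a subsequence (monotonicity)
  orig <- A$points
  got <- en$contours[["1"]]$points
  idx <- match(data.frame(t(orig)), data.frame(t(got)))
  expect_true(all(diff(idx) > 0))
  # brute-force oracle: every inserted foreign point is inside some cylinder
  in_cyl <- function(q, p1, p2, r, dh) {
    d <- p2 - p1; L <- sqrt(sum(d^2)); u <- d / L
    t <- sum((q - p1) * u)
    rad <- sqrt(sum((q - p1 - t * u)^2))
    rad <= r && t >= -dh && t <= L + dh
  }
  for (q_i in 3:4) {
    q <- got[q_i, ]
    any_hit <- FALSE
    for (e in seq_len(nrow(got))) {
      if (e %in% c(q_i, q_i - 1)) next
      e2 <- if (e == nrow(got)) 1L else e + 1L
      if (in_cyl(q, got[e, ], got[e2, ], 0.2, 0.1)) any_hit <- TRUE
    }
    expect_true(any_hit)
  }
})

test_that("points outside all cylinders are never inserted; no neighbours is a no-op", {
  A <- vessel_contour("1", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  far <- vessel_contour("2", cbind(c(1.21, 2, 2), c(0.5, 0, 1), 0))
  ds <- contour_dataset(list(A, far), axes_canonical())
  en <- enrich_contours(ds, r = 0.2, dh = 0.1)
  # the point at perpendicular distance 0.21 > r from A's nearest edge stays out
  expect_false(any(abs(en$contours[["1"]]$points[, 1] - 1.21) < 1e-12))
  solo <- contour_dataset(list(A), axes_canonical())
  expect_equal(enrich_contours(solo, 1, 1)$contours[["1"]]$points, A$points)
})

test_that("enrichment commutes with rigid transforms of the whole dataset", {
  sim <- sim_small()
  ds <- sim$dataset
  small <- ds
  small$contours <- ds$contours[1:4]
  en1 <- enrich_contours(small, r = 1, dh = 1)
  set.seed(11)
  Tr <- rigid_transform(lumenfit:::random_rotation(), runif(3, -5, 5))
  small2 <- small
  small2$contours <- lapply(small$contours, function(ct)
    vessel_contour(ct$cell_id, apply_transform(Tr, ct$points), ct$stage))
  en2 <- enrich_contours(small2, r = 1, dh = 1)
  for (id in names(small$contours))
    expect_equal(en2$contours[[id]]$points,
                 apply_transform(Tr, en1$contours[[id]]$points),
                 tolerance = 1e-9)
})

test_that("edge interpolation inserts floor(n_rel * length) equally spaced points", {
  sq <- square_contour("s")
  expect_equal(interpolate_contour(sq, 0)$points, sq$points)
  i1 <- interpolate_contour(sq, 1)
  expect_equal(nrow(i1$points), 8L)
  i2 <- interpolate_contour(sq, 2)
  expect_equal(nrow(i2$points), 12L)
  # edge length 1, n_rel = 2 -> interior points at fractions 1/3, 2/3
  expect_equal(i2$points[2:3, 1], c(1, 2) / 3)
  # non-integer edge lengths: floor rule
  tri <- vessel_contour("t", cbind(c(0, 2.6, 0), c(0, 0, 1.2), 0))
  it <- interpolate_contour(tri, 1)
  lens <- c(2.6, sqrt(2.6^2 + 1.2^2), 1.2)
  expect_equal(nrow(it$points), 3L + sum(floor(lens)))
})

test_that("periodic smoothing splines honour the residual budget and periodicity", {
  t <- seq(0, 2 * pi, length.out = 61)[-61]
  circ <- vessel_contour("c", cbind(5 * cos(t), 5 * sin(t), 0))
  sp <- fit_periodic_spline(circ, eps_spline = 1e-6)
  u <- seq(0, 1, length.out = 64)
  pe <- predict(sp, u)
  expect_lt(max(abs(sqrt(pe[, 1]^2 + pe[, 2]^2) - 5)), 1e-3 * 5)
  expect_equal(predict(sp, 0), predict(sp, 1), tolerance = 1e-10)
  # noisy square: SSR <= eps * n by construction, even for large eps
  set.seed(2)
  sq <- interpolate_contour(square_contour("s", side = 4), 3)
  noisy <- vessel_contour("n", sq$points +
                            matrix(rnorm(length(sq$points), 0, 0.05), ncol = 3))
  for (eps in c(0.01, 100)) {
    spn <- fit_periodic_spline(noisy, eps_spline = eps)
    expect_lte(spn$ssr, eps * spn$n_src + 1e-9)
  }
  # degenerate input
  line <- vessel_contour("l", cbind(c(0, 1, 2, 3), 0, 0))
  expect_error(fit_periodic_spline(line), "degenerate")
})

test_that("equidistant spline resampling spaces points uniformly from u = 0", {
  t <- seq(0, 2 * pi, length.out = 81)[-81]
  circ <- vessel_contour("c", cbind(cos(t), sin(t), 0))
  sp <- fit_periodic_spline(circ, eps_spline = 1e-8)
  rs <- resample_spline(sp, 10)
  expect_equal(nrow(rs$points), floor(10 * spline_arclength(sp)))
  expect_identical(rs$u[1], 0)
  expect_true(all(diff(rs$u) > 0) && all(rs$u < 1))
  g <- sqrt(rowSums((rs$points[c(2:nrow(rs$points), 1), ] - rs$points)^2))
  expect_lt(max(g) / min(g), 1.005)
  expect_error(resample_spline(sp, 0.3), "resolution")
})
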