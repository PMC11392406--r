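test_that("luminal area and diameter match analytic and brute-force values", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2), 0)
  expect_identical(luminal_area(sq), 4)
  expect_equal(luminal_diameter(sq), 2 * sqrt(2))
  u <- seq(0, 2 * pi, length.out = 63)[-63]
  circ62 <- cbind(cos(u), sin(u), 0)
  expect_close(luminal_area(circ62), pi, 0.002 * pi)
  expect_close(luminal_diameter(circ62), 2, 0.01)
  # random simple (star-convex) polygon: brute-force O(n^2) diameter oracle
  set.seed(3)
  r <- runif(40, 1, 2)
  a <- sort(runif(40, 0, 2 * pi))
  poly <- cbind(r * cos(a), r * sin(a), 0)
  d_brute <- max(as.matrix(stats::dist(poly)))
  expect_equal(luminal_diameter(poly), d_brute)
  # self-intersecting polygon raises an error
  bow <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0), 0)
  expect_error(luminal_area(bow), "self-intersect")
  # orientation independence
  expect_equal(luminal_area(sq[4:1, ]), 4)
})

test_that("compactness hits the printed flat-figure values and the disc limit", {
  expect_equal(compactness(1, 4), 4 * pi / 16)          # unit square
  expect_equal(compactness(4, 10), 16 * pi / 100)       # 4 x 1 rectangle
  expect_error(compactness(1, 0), "positive")
  # finely triangulated unit disc -> compactness 1
  n <- 720
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  verts <- rbind(c(0, 0, 0), cbind(cos(a), sin(a), 0))
  tris <- cbind(1L, 1L + seq_len(n), 1L + c(2:n, 1L))
  area <- sum(lumenfit:::triangle_areas(verts, tris))
  perim <- sum(sqrt(rowSums((verts[1L + c(2:n, 1L), ] -
                               verts[1L + 1:n, ])^2)))
  expect_close(compactness(area, perim), 1, 1e-3)
})

test_that("elongation follows the angular-span x median-radius convention", {
  grid <- local({
    z <- seq(0, 40, by = 1)
    build_grid(t(vapply(z, cylinder_theta(6.366), numeric(7))), z, 2)
  })
  mkmesh <- function(a1, a2, z1, z2) {
    keys <- NULL; verts <- NULL
    for (k in (z1 + 1):(z2 + 1)) {
      ring <- grid$rings[[k]]
      ang <- atan2(ring$points[, 2], ring$points[, 1]) %% (2 * pi)
      sel <- which(ang >= a1 & ang <= a2)
      keys <- rbind(keys, cbind(k, sel))
      verts <- rbind(verts, ring$points[sel, ])
    }
    list(vertices = verts, keys = keys,
         triangles = matrix(1:3, 1))   # triangles unused by elongation
  }
  # 90-degree arc at radius 6.366 (arc ~ 10 um); dz = 10 -> elong ~ 1.
  # The covering arc of the snapped ring points is (n_sel - 1) spacings,
  # which gives the exact expected value for this construction.
  n_k <- grid$rings[[1]]$n_k
  m1 <- mkmesh(0.4, 0.4 + pi / 2, 10, 20)
  e1 <- elongation(m1, grid)
  n_sel <- sum(m1$keys[, 1] == 11)
  span_exp <- (n_sel - 1) * 2 * pi / n_k
  expect_close(e1$elong, 10 / (span_exp * 6.366), 1e-6)
  expect_close(e1$elong, 1, 0.12)
  # dz = 20 -> elong ~ 2
  m2 <- mkmesh(0.4, 0.4 + pi / 2, 10, 30)
  expect_close(elongation(m2, grid)$elong, 20 / (span_exp * 6.366), 1e-6)
  # full ring band: denominator is the full circumference
  m3 <- local({
    keys <- NULL; verts <- NULL
    for (k in 1:32) {
      ring <- grid$rings[[k]]
      keys <- rbind(keys, cbind(k, seq_len(ring$n_k)))
      verts <- rbind(verts, ring$points)
    }
    list(vertices = verts, keys = keys, triangles = matrix(1:3, 1))
  })
  e3 <- elongation(m3, grid)
  expect_true(e3$wraps)
  expect_close(e3$elong, 31 / (2 * pi * 6.366), 0.02)
})

test_that("sector classification fractions, class and detailed labels", {
  z <- seq(0, 4, by = 1)
  grid <- build_grid(t(vapply(z, cylinder_theta(5), numeric(7))), z, 2)
  # synthetic mesh entirely in the dorsal quadrant
  tri_at <- function(ang, k = 2L) {
    ring <- grid$rings[[k]]
    ctr <- c(5 * cos(ang), 5 * sin(ang))
    v <- rbind(c(ctr[1] - 0.1, ctr[2], ring$z), c(ctr[1] + 0.1, ctr[2], ring$z),
               c(ctr[1], ctr[2] + 0.1, ring$z + 0.5))
    v
  }
  mk <- function(angles) {
    verts <- do.call(rbind, lapply(angles, tri_at))
    list(vertices = verts, keys = cbind(2L, seq_len(nrow(verts))),
         triangles = matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE))
  }
  dorsal_only <- mk(c(pi / 2, pi / 2 + 0.2, pi / 2 - 0.2))
  cd <- classify_cell(dorsal_only, grid)
  expect_equal(unname(cd$fractions), c(1, 0, 0, 0))
  expect_identical(cd$class, "dorsal")
  expect_identical(cd$detailed, "D")
  # 60/40 dorsal/left split -> dorsal class, compound D-LR detailed
  m2 <- mk(c(rep(pi / 2, 3), rep(pi, 2)))
  c2 <- classify_cell(m2, grid)
  expect_close(c2$fractions[["dorsal"]], 0.6, 1e-9)
  expect_identical(c2$class, "dorsal")
  expect_identical(c2$detailed, "D-LR")
  # no sector above 50% -> unclassified
  m3 <- mk(c(rep(pi / 2, 2), rep(3 * pi / 2, 2), pi))
  c3 <- classify_cell(m3, grid)
  expect_identical(c3$class, "unclassified")
  # left 40 + right 20 does not make a left/right class (tested alone)
  m4 <- mk(c(rep(pi, 2), 0, rep(pi / 2, 2)))
  expect_identical(classify_cell(m4, grid)$class, "unclassified")
  # fractions sum to 1 and are triangle-permutation invariant
  m5 <- mk(c(0.1, 1.2, 2.5, 3.4, 4.4, 5.2))
  c5 <- classify_cell(m5, grid)
  expect_equal(sum(c5$fractions), 1, tolerance = 1e-9)
  perm <- m5; perm$triangles <- perm$triangles[c(3, 1, 2, 6, 4, 5), ]
  expect_equal(classify_cell(perm, grid)$fractions, c5$fractions)
})

test_that("qcd uses type-7 quartiles and dev_rel the printed convention", {
  q <- qcd(c(1, 1, 3, 3))
  expect_equal(q$Q1, 1)   # type-7 interpolation
  expect_equal(q$Q3, 3)
  expect_equal(q$qcd, 0.5)
  expect_equal(qcd(rep(2, 6))$qcd, 0)
  expect_error(qcd(c(1, 2, 3)), "4")
  expect_error(qcd(c(-1, 2, 3, 4)), "positive")
  expect_equal(dev_rel(90, 100), -1 / 9)
  expect_equal(dev_rel(100, 100), 0)
  expect_equal(dev_rel(100, 90), 0.1)
  expect_error(dev_rel(0, 1), "non-zero")
})

test_that("exclusion filters reproduce brute-force kept/excluded sets", {
  cells <- data.frame(cell_id = as.character(1:5),
                      projection_distance = c(0.1, 0.742, 0.743, 1.5, 0.5))
  f <- filter_cells(cells)
  expect_setequal(f$kept$cell_id, c("1", "2", "5"))
  expect_setequal(f$excluded$cell_id, c("3", "4"))
  # synthetic distances vs brute force
  set.seed(6)
  cells2 <- data.frame(cell_id = as.character(1:50),
                       projection_distance = runif(50, 0, 1.5))
  f2 <- filter_cells(cells2, 0.742)
  expect_setequal(f2$kept$cell_id,
                  cells2$cell_id[cells2$projection_distance <= 0.742])

  # plane filter: cells as point sets around planes
  contours <- list(
    a = cbind(0, 0, c(0.0, 0.4, 0.8)),
    b = cbind(0, 0, c(0.45, 0.9, 1.3)),
    c = cbind(0, 0, c(5, 6, 7)))
  z <- c(0.5, 2, 6)
  f3 <- filter_cross_sections(z, contours, min_cells = 2, radius_z = 0.5)
  expect_equal(f3$n_nearby, c(2, 0, 1))
  expect_equal(f3$kept, 1L)
  expect_setequal(f3$excluded, 2:3)
  # brute force on the synthetic vessel
  sim <- sim_small()
  zz <- seq(2, 38, by = 3)
  ff <- filter_cross_sections(zz, sim$dataset$contours)
  brute <- vapply(zz, function(zk)
    sum(vapply(sim$dataset$contours, function(ct)
      min(abs(ct$points[, 3] - zk)) <= 0.5, logical(1))), numeric(1))
  expect_equal(ff$n_nearby, brute)
  expect_equal(ff$kept, which(brute >= 2))
})

test_that("scale invariances: compactness and elongation are scale-free", {
  tp <- truth_pipeline_clean()
  id <- names(tp$meshes)[1]
  mesh <- tp$meshes[[id]]
  s <- 2.5
  scaled_grid <- tp$grid
  for (k in seq_along(scaled_grid$rings)) {
    scaled_grid$rings[[k]]$points <- s * scaled_grid$rings[[k]]$points
    th <- scaled_grid$rings[[k]]$theta
    th[1:5] <- s * th[1:5]
    scaled_grid$rings[[k]]$theta <- th
  }
  smesh <- mesh
  smesh$vertices <- s * smesh$vertices
  a1 <- mesh_area(mesh); a2 <- mesh_area(smesh)
  expect_close(a2 / a1, s^2, 1e-9)
  p1 <- cell_perimeter(tp$projs[[id]])
  expect_equal(compactness(a1, p1), compactness(a2, s * p1), tolerance = 1e-9)
  e1 <- elongation(mesh, tp$grid)$elong
  e2 <- elongation(smesh, scaled_grid)$elong
  expect_equal(e1, e2, tolerance = 1e-9)
})
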