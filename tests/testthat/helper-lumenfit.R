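# Shared fixtures: built in code, cached across test files within a run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

axes_canonical <- function() {
  list(ap = rbind(c(0, 0, 0), c(0, 0, 1)),
       dv = rbind(c(0, 0, 0), c(0, 1, 0)),
       lr = rbind(c(0, 0, 0), c(1, 0, 0)))
}

square_contour <- function(id = "sq", side = 1, z = 0) {
  vessel_contour(id, cbind(c(0, side, side, 0), c(0, 0, side, side), z))
}

# Constant-parameter circular cylinder spec (analytic oracle surface).
cylinder_theta <- function(radius = 10) {
  function(z) c(m_x = 0, m_y = 0, a = radius, b = radius, c = radius,
                alpha = 1, beta = 1)
}

# Small synthetic vessel in canonical coordinates (identity mounting).
sim_small <- function() memo("sim_small", {
  simulate_vessel(tube_spec(length = 40, n_cells = 10, noise_sd = 0.25,
                            seed = 3, transform = rigid_transform()))
})

# Reconstruction of the small vessel at reduced axial resolution.
fit_small <- function() memo("fit_small", {
  vessel_recon(sim_small()$dataset, vessel_control(M_rel = 1))
})

# Noise-free small vessel (sharp oracle for projection / meshing).
sim_clean <- function() memo("sim_clean", {
  simulate_vessel(tube_spec(length = 40, n_cells = 10, noise_sd = 0,
                            seed = 5, transform = rigid_transform()))
})

# Truth-grid reconstruction objects for the clean vessel: grid built from
# the true parameter profile (no fitting), plus projections and meshes.
truth_pipeline_clean <- function() memo("truth_pipeline_clean", {
  sim <- sim_clean()
  # fine grid and tight splines so boundary snapping of adjacent cells
  # agrees; the area-partition property is a property of the meshing, not
  # of annotation smoothing
  ctl <- vessel_control(M_rel = 2, n_cross_rel = 4, eps_spline = 0.005)
  z <- plan_planes(rbind(c(0, 0, 0), c(0, 0, sim$spec$length)), ctl$M_rel)
  theta <- t(vapply(z, sim$spec$theta_fn, numeric(7)))
  grid <- build_grid(theta, z, ctl$n_cross_rel)
  prep <- preprocess_contours(sim$dataset, ctl)
  projs <- list(); meshes <- list()
  for (id in names(prep$splines)) {
    p <- project_contour_to_grid(prep$splines[[id]], grid)
    projs[[id]] <- p
    meshes[[id]] <- triangulate_cell(p, grid)
  }
  list(sim = sim, grid = grid, prep = prep, projs = projs, meshes = meshes)
})

# Acceptance-scale synthetic study: 100 um sinusoidal tube, 25 cells,
# 0.25 um annotation noise, random mounting transform, default tuning.
sim_acceptance <- function() memo("sim_acceptance", {
  simulate_vessel(tube_spec(length = 100, n_cells = 25, noise_sd = 0.25,
                            seed = 101))
})

fit_acceptance <- function() memo("fit_acceptance", {
  vessel_recon(sim_acceptance()$dataset, vessel_control())
})

# Per-plane deviation of a reconstruction from the generator truth: each
# fitted ring is mapped back to canonical coordinates (undoing the estimated
# frame and the mounting transform) and compared, as an xy polygon, with the
# true cross-section at the ring's mean canonical z.
plane_dev_vs_truth <- function(fit, sim) {
  M <- lumenfit:::compose_transform(fit$frame$transform, sim$transform)
  Minv <- lumenfit:::invert_transform(M)
  L <- sim$spec$length
  vapply(seq_along(fit$grid$rings), function(i) {
    ring <- fit$grid$rings[[i]]
    pts <- apply_transform(Minv, ring$points)
    zc <- min(max(mean(pts[, 3]), 0), L)
    truth <- lumenfit:::as_shape_params(sim$spec$theta_fn(zc))
    dev_cross(pts[, 1:2], shape_polygon(truth, 360))
  }, numeric(1))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}

# Python/shapely oracle for polygon boolean areas (independent of the
# package's clipping); returns NA if python is unavailable.
shapely_symdiff_area <- function(A, B) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NA_real_)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  utils::write.table(A, f1, row.names = FALSE, col.names = FALSE, sep = ",")
  utils::write.table(B, f2, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\nfrom shapely.geometry import Polygon\n",
    "A=Polygon(np.loadtxt('%s',delimiter=','))\n",
    "B=Polygon(np.loadtxt('%s',delimiter=','))\n",
    "print(A.symmetric_difference(B).area)"), f1, f2)
  out <- tryCatch(system2(py, "-", input = code, stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NA_character_, warning = function(w) NA_character_)
  suppressWarnings(as.numeric(out[length(out)]))
}
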