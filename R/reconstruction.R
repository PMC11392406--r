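#' Plan cross-sectional plane positions
#'
#' `M = floor(M_rel * z-extent)` equidistant planes spanning the z-range of
#' the (transformed) points, endpoints included.
#'
#' @param points n x 3 matrix of points in vessel coordinates, or a numeric
#'   vector of z values.
#' @param M_rel cross-sections per micrometre.
#' @return Numeric vector of plane positions `z_1 < ... < z_M`.
#' @export
plan_planes <- function(points, M_rel = 2) {
  z <- if (is.matrix(points)) points[, 3] else as.numeric(points)
  rng <- range(z)
  if (diff(rng) <= 0) stop("need >= 2 distinct z values", call. = FALSE)
  M <- floor(M_rel * diff(rng))
  if (M < 2L) stop("axial resolution too low (M < 2)", call. = FALSE)
  seq(rng[1], rng[2], length.out = M)
}

#' Truncated Gaussian axial weight
#'
#' `exp(-(dz)^2 / (2 * omega^2))` for `|dz| <= Z_omega * omega`, else 0.
#'
#' @param dz axial distance(s) from the plane (um).
#' @param omega weight standard deviation (um), > 0.
#' @param Z_omega truncation in units of omega.
#' @return Weights in `[0, 1]`.
#' @export
gauss_weight <- function(dz, omega, Z_omega = 2) {
  stopifnot(omega > 0)
  w <- exp(-dz^2 / (2 * omega^2))
  w[abs(dz) > Z_omega * omega] <- 0
  w
}

# Octant index (1..8) of xy-points about the origin; boundaries at
# 0, 45, ..., 315 degrees, boundary angles assigned to the
# counter-clockwise-next octant.
octant_index <- function(xy) {
  ang <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
  idx <- floor(ang / (pi / 4)) + 1L
  idx[idx > 8L] <- 1L
  idx
}

#' Adaptive weight width for a cross-sectional plane
#'
#' The smallest `omega_k` such that every octant of the xy-plane (45-degree
#' sectors about the origin) holds at least `n_oct` points with non-zero
#' truncated-Gaussian weight: per octant the `n_oct`-th smallest axial
#' distance is found and the maximum over octants is divided by `Z_omega`.
#'
#' @param points n x 3 matrix in vessel coordinates.
#' @param z_k plane position (um).
#' @param n_oct minimum points per octant.
#' @param Z_omega weight truncation factor.
#' @return `omega_k` in um (floored at 1e-6).
#' @export
adaptive_width <- function(points, z_k, n_oct = 30L, Z_omega = 2) {
  oct <- octant_index(points[, 1:2, drop = FALSE])
  dz <- abs(points[, 3] - z_k)
  d_need <- numeric(8L)
  for (o in 1:8) {
    d_o <- dz[oct == o]
    if (length(d_o) < n_oct)
      stop(sprintf("octant %d holds only %d points (< n_oct = %d)", o,
                   length(d_o), n_oct), call. = FALSE)
    d_need[o] <- sort(d_o, partial = n_oct)[n_oct]
  }
  max(max(d_need) / Z_omega, 1e-6)
}

#' Fit a local cross-sectional shape
#'
#' Minimises the truncated-Gaussian-weighted sum of projection distances of
#' the (xy-projected) spline points to the shape, starting from the mean
#' shape, subject to the plausibility constraint
#' `dev_cross(shape, mean_shape) <= lambda`. The constraint is enforced by a
#' penalty refit followed, if necessary, by a bisection blend towards the
#' (always feasible) mean shape, so the returned parameters satisfy the
#' bound to within 1e-6.
#'
#' @param points n x 3 matrix in vessel coordinates.
#' @param z_k plane position (um).
#' @param omega_k weight width (um).
#' @param mean_shape mean shape ([shape_params()], midpoint 0).
#' @param lambda constraint level (fraction); `lambda = 0` returns the mean
#'   shape unchanged.
#' @param control a [vessel_control()] (uses `n_poly`, `Z_omega`,
#'   `squared_residuals`).
#' @return List: `theta` ([shape_params()]), `omega`, `z`, `converged`,
#'   `objective`, `dev` (deviation from the mean shape), `n_points`.
#' @export
fit_cross_section <- function(points, z_k, omega_k, mean_shape,
                              lambda = 0.2, control = vessel_control()) {
  w <- gauss_weight(points[, 3] - z_k, omega_k, control$Z_omega)
  sel <- w > 0
  w <- w[sel]
  xy <- points[sel, 1:2, drop = FALSE]
  mean_shape <- as_shape_params(mean_shape)
  if (lambda <= 0)
    return(list(theta = mean_shape, omega = omega_k, z = z_k,
                converged = TRUE, objective = NA_real_, dev = 0,
                n_points = nrow(xy)))
  sq <- control$squared_residuals
  lower <- c(-Inf, -Inf, 0.2, 0.2, 0.2, shape_exponent_bounds[1],
             shape_exponent_bounds[1])
  upper <- c(Inf, Inf, Inf, Inf, Inf, shape_exponent_bounds[2],
             shape_exponent_bounds[2])
  scale0 <- max(mean_shape[c("a", "b", "c")])
  base_fn <- function(par) {
    pc <- pmin(pmax(par, lower), upper)
    excess <- sum(pmax(0, par - upper) + pmax(0, lower - par))
    .shape_objective_cpp(pc, xy, w, control$n_poly, sq) * (1 + excess) + excess
  }
  # optimise against a coarsened polygon: the chord sag of a 90-gon at
  # vessel calibre (~6 nm) is far below annotation noise, and the final
  # objective and deviation are re-evaluated at full density
  n_poly_opt <- max(90L, control$n_poly %/% 4L)
  opt_fn <- function(par)
    .shape_objective_cpp(pmin(pmax(par, lower), upper), xy, w, n_poly_opt, sq)
  ctl <- list(maxit = 40, factr = 1e7,
              parscale = c(scale0, scale0, scale0, scale0, scale0, 1, 1))
  res <- stats::optim(as.numeric(mean_shape), opt_fn, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  theta <- pmin(pmax(res$par, lower), upper)
  dev <- dev_cross(as_shape_params(theta), mean_shape, control$n_poly)
  converged <- res$convergence == 0L
  if (dev > lambda) {
    pen <- 100 * max(res$value, 1) / lambda^2
    pen_fn <- function(par) {
      pc <- pmin(pmax(par, lower), upper)
      d <- dev_cross(as_shape_params(pc), mean_shape, control$n_poly)
      base_fn(par) + pen * max(0, d - lambda)^2
    }
    res2 <- stats::optim(theta, pen_fn, method = "Nelder-Mead",
                         control = list(maxit = 300, reltol = 1e-7,
                                        parscale = ctl$parscale))
    theta <- pmin(pmax(res2$par, lower), upper)
    dev <- dev_cross(as_shape_params(theta), mean_shape, control$n_poly)
  }
  if (dev > lambda) {
    # blend towards the mean shape until feasible (dev_cross is continuous
    # in the blend and 0 at the mean shape)
    th0 <- as.numeric(mean_shape)
    dtheta <- theta - th0
    lo <- 0; hi <- 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      d <- dev_cross(as_shape_params(th0 + mid * dtheta), mean_shape,
                     control$n_poly)
      if (d <= lambda) lo <- mid else hi <- mid
    }
    theta <- th0 + lo * dtheta
    dev <- dev_cross(as_shape_params(theta), mean_shape, control$n_poly)
  }
  theta <- as_shape_params(theta)
  list(theta = theta, omega = omega_k, z = z_k, converged = converged,
       objective = base_fn(as.numeric(theta)), dev = dev,
       n_points = nrow(xy))
}

#' Smooth shape parameters along the axis
#'
#' Convolves each of the 7 parameter sequences with a truncated Gaussian
#' kernel (SD `sigma`, truncated at `Z_sigma * sigma`), renormalised over the
#' available window near the boundaries and over planes that were skipped
#' (rows of `NA`).
#'
#' @param theta_mat M x 7 matrix of raw parameters (rows may be `NA` for
#'   skipped planes).
#' @param z plane positions (equidistant).
#' @param sigma kernel SD (um); `sigma = 0` disables smoothing.
#' @param Z_sigma truncation factor.
#' @return M x 7 matrix of smoothed parameters.
#' @export
smooth_shape_params <- function(theta_mat, z, sigma = 10, Z_sigma = 2) {
  theta_mat <- as.matrix(theta_mat)
  M <- nrow(theta_mat)
  if (sigma <= 0 || M < 2L) return(theta_mat)
  dz <- z[2] - z[1]
  half <- floor(Z_sigma * sigma / dz)
  offs <- (-half):half
  kern <- exp(-(offs * dz)^2 / (2 * sigma^2))
  ok <- stats::complete.cases(theta_mat)
  out <- theta_mat
  for (k in seq_len(M)) {
    if (!ok[k]) next
    j <- k + offs
    keep <- j >= 1L & j <= M
    j <- j[keep]
    kw <- kern[keep]
    kw <- kw * ok[j]
    if (sum(kw) <= 0) next
    kw <- kw / sum(kw)
    out[k, ] <- colSums(theta_mat[j, , drop = FALSE] * kw, na.rm = TRUE)
  }
  out
}

#' Build the organized vessel grid
#'
#' Samples `floor(n_cross_rel * circumference)` equidistant points on every
#' (smoothed) cross-sectional shape, producing an organized point cloud of
#' ordered rings.
#'
#' @param theta_mat M x 7 matrix of (smoothed) shape parameters; `NA` rows
#'   are skipped.
#' @param z plane positions.
#' @param n_cross_rel grid points per um of circumference.
#' @return Object of class `vessel_grid`: list of rings, each with `points`
#'   (n_k x 3), `u` parameters, `theta`, `z`, `n_k`.
#' @export
build_grid <- function(theta_mat, z, n_cross_rel = 2) {
  theta_mat <- as.matrix(theta_mat)
  rings <- vector("list", nrow(theta_mat))
  for (k in seq_len(nrow(theta_mat))) {
    if (anyNA(theta_mat[k, ])) next
    th <- as_shape_params(theta_mat[k, ])
    eq <- shape_equidistant(th, n_cross_rel)
    rings[[k]] <- list(points = cbind(eq$points, z = z[k]), u = eq$u,
                       theta = th, z = z[k], n_k = nrow(eq$points),
                       circumference = eq$circumference)
  }
  keep <- !vapply(rings, is.null, logical(1))
  structure(list(rings = rings[keep], z = z[keep],
                 n_cross_rel = n_cross_rel),
            class = "vessel_grid")
}

#' @export
print.vessel_grid <- function(x, ...) {
  nk <- vapply(x$rings, function(r) r$n_k, integer(1))
  cat(sprintf("Organized vessel grid: %d cross-sections, z in [%.2f, %.2f] um, %d points\n",
              length(x$rings), min(x$z), max(x$z), sum(nk)))
  invisible(x)
}

#' Estimate all cross-sections along the vessel
#'
#' Runs plane planning, adaptive width selection, constrained local shape
#' fitting and parameter smoothing over the whole vessel. Planes whose
#' octant population is insufficient are skipped and reported rather than
#' aborting the run.
#'
#' @param points n x 3 matrix of transformed spline sample points.
#' @param mean_shape the mean shape.
#' @param control a [vessel_control()].
#' @return List: `z`, `theta_raw`, `theta_smooth` (M x 7 matrices), `omega`,
#'   `converged`, `dev_raw`, `dev_smooth` (deviations from the mean shape),
#'   `skipped` (indices of skipped planes), `grid` (a [build_grid()] result).
#' @export
estimate_cross_sections <- function(points, mean_shape,
                                    control = vessel_control()) {
  z <- plan_planes(points, control$M_rel)
  M <- length(z)
  theta_raw <- matrix(NA_real_, M, 7L,
                      dimnames = list(NULL, names(as_shape_params(mean_shape))))
  omega <- rep(NA_real_, M)
  convg <- rep(NA, M)
  devs <- rep(NA_real_, M)
  skipped <- integer(0)
  for (k in seq_len(M)) {
    om <- tryCatch(adaptive_width(points, z[k], control$n_oct, control$Z_omega),
                   error = function(e) NA_real_)
    if (is.na(om)) { skipped <- c(skipped, k); next }
    fit <- fit_cross_section(points, z[k], om, mean_shape, control$lambda,
                             control)
    theta_raw[k, ] <- as.numeric(fit$theta)
    omega[k] <- om
    convg[k] <- fit$converged
    devs[k] <- fit$dev
  }
  theta_smooth <- smooth_shape_params(theta_raw, z, control$sigma,
                                      control$Z_sigma)
  dev_smooth <- rep(NA_real_, M)
  for (k in seq_len(M)) {
    if (anyNA(theta_smooth[k, ])) next
    dev_smooth[k] <- dev_cross(as_shape_params(theta_smooth[k, ]), mean_shape,
                               control$n_poly)
  }
  grid <- build_grid(theta_smooth, z, control$n_cross_rel)
  list(z = z, theta_raw = theta_raw, theta_smooth = theta_smooth,
       omega = omega, converged = convg, dev_raw = devs,
       dev_smooth = dev_smooth, skipped = skipped, grid = grid)
}
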