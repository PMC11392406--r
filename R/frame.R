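#' Estimate the vessel-intrinsic coordinate system and mean shape
#'
#' Finds the rigid transform into vessel coordinates (x left-right, y
#' ventral-to-dorsal, z anterior-posterior) together with the single
#' cross-sectional "mean shape" that best fits all resampled spline points
#' projected onto the xy-plane, by minimising the sum of squared distances of
#' the projected points to the shape. The transform and the shape are
#' estimated by alternating optimisation: (i) the shape at fixed frame, (ii)
#' small frame rotations plus in-plane translation at fixed shape. The
#' z-axis is initialised from the first principal component of the points
#' (sign-matched to the annotated anterior-posterior vector) and the y-axis
#' from the annotated dorsal-ventral vector orthogonalised against z. After
#' convergence the axes' signs are checked against the annotated vectors and
#' the mean shape is re-fitted at the final frame. The mean shape's midpoint
#' is pinned to the origin; the translation absorbs it.
#'
#' @param samples named list of stage-`"spline_sample"` contours (original
#'   coordinates), or a single n x 3 point matrix.
#' @param axes axis annotation list with 2 x 3 matrices `ap`, `dv`, `lr`.
#' @param max_iter maximum alternating iterations.
#' @param rel_tol relative objective improvement below which to stop.
#' @param n_poly polygon density for shape projections.
#' @param max_points at most this many points are used during the
#'   alternating optimisation (deterministic thinning); the final mean-shape
#'   refit uses all points.
#' @return Object of class `vessel_frame`: fields `transform`
#'   ([rigid_transform()]), `mean_shape` ([shape_params()], midpoint 0),
#'   `objective`, `iterations`, `converged`.
#' @export
estimate_frame <- function(samples, axes, max_iter = 50L, rel_tol = 1e-6,
                           n_poly = 360L, max_points = 3000L) {
  if (is.matrix(samples)) {
    P <- samples
    n_cells <- 2L
  } else {
    P <- do.call(rbind, lapply(samples, function(ct) ct$points))
    n_cells <- length(samples)
  }
  if (nrow(P) < 200L || n_cells < 2L)
    stop("frame estimation needs >= 200 sample points from >= 2 cells",
         call. = FALSE)
  ap <- axes$ap[2, ] - axes$ap[1, ]
  dv <- axes$dv[2, ] - axes$dv[1, ]
  lr <- axes$lr[2, ] - axes$lr[1, ]

  # --- initialisation: PCA axis + annotated dorsal-ventral direction
  ctr <- colMeans(P)
  pc <- svd(sweep(P, 2L, ctr))$v
  zax <- pc[, 1]
  if (sum(zax * ap) < 0) zax <- -zax
  if (abs(sum(zax * ap) / sqrt(sum(ap^2))) < 0.05)
    stop("anterior-posterior annotation nearly perpendicular to the vessel axis;
 cannot disambiguate axis signs", call. = FALSE)
  yax <- dv - sum(dv * zax) * zax
  if (sqrt(sum(yax^2)) < 1e-8 * sqrt(sum(dv^2)))
    stop("dorsal-ventral annotation nearly parallel to the vessel axis",
         call. = FALSE)
  yax <- yax / sqrt(sum(yax^2))
  xax <- cross3(yax, zax)
  R <- rbind(x = xax, y = yax, z = zax)
  tvec <- as.numeric(-R %*% ctr)

  # deterministic thinning for the alternating loop
  idx <- if (nrow(P) > max_points)
    unique(round(seq(1L, nrow(P), length.out = max_points))) else seq_len(nrow(P))
  Psub <- P[idx, , drop = FALSE]

  theta <- NULL
  obj <- Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    Pt <- sweep(Psub %*% t(R), 2L, tvec, "+")
    theta <- fit_mean_shape(Pt[, 1:2, drop = FALSE], init = theta,
                            n_poly = n_poly)
    # absorb midpoint into the translation
    tvec[1:2] <- tvec[1:2] - theta[c("m_x", "m_y")]
    theta[c("m_x", "m_y")] <- 0
    poly <- shape_polygon(theta, n_poly)
    refine <- stats::optim(
      c(0, 0, 0, 0, 0),
      function(par) {
        Rd <- rotation_xyz(par[1], par[2], par[3])
        Pt2 <- sweep(Psub %*% t(Rd %*% R), 2L,
                     as.numeric(Rd %*% tvec) + c(par[4], par[5], 0), "+")
        sum(.proj_polygon_cpp(Pt2[, 1:2, drop = FALSE], poly, TRUE)[, 1]^2)
      },
      method = "BFGS", control = list(maxit = 60, reltol = 1e-10))
    par <- refine$par
    Rd <- rotation_xyz(par[1], par[2], par[3])
    R <- Rd %*% R
    tvec <- as.numeric(Rd %*% tvec) + c(par[4], par[5], 0)
    new_obj <- refine$value
    if (is.finite(obj) && (obj - new_obj) <= rel_tol * max(obj, 1e-12)) {
      obj <- min(obj, new_obj)
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged)
    warning("frame estimation did not converge within ", max_iter,
            " iterations; returning best iterate")

  # --- axis sign disambiguation against the annotations
  flip_z180 <- diag(c(-1, -1, 1))   # 180 deg about z: swaps dorsal/ventral
  flip_y180 <- diag(c(-1, 1, -1))   # 180 deg about y: shape-symmetric
  if (abs((R %*% ap)[3]) < 0.1 * sqrt(sum(ap^2)))
    stop("anterior-posterior annotation nearly perpendicular to the vessel axis;
 cannot disambiguate axis signs", call. = FALSE)
  if (sum((R %*% dv)[2]) < 0) {
    R <- flip_z180 %*% R
    tvec <- as.numeric(flip_z180 %*% tvec)
    theta[c("a", "b")] <- theta[c("b", "a")]
    theta[c("alpha", "beta")] <- theta[c("beta", "alpha")]
  }
  if ((R %*% ap)[3] < 0) {
    R <- flip_y180 %*% R
    tvec <- as.numeric(flip_y180 %*% tvec)
  }
  if ((R %*% lr)[1] < 0)
    warning("left-right annotation inconsistent with the estimated frame")

  # --- final mean-shape refit on all points at the fixed frame
  Pall <- sweep(P %*% t(R), 2L, tvec, "+")
  theta <- fit_mean_shape(Pall[, 1:2, drop = FALSE], init = theta,
                          n_poly = n_poly)
  tvec[1:2] <- tvec[1:2] - theta[c("m_x", "m_y")]
  theta[c("m_x", "m_y")] <- 0
  Pall <- sweep(P %*% t(R), 2L, tvec, "+")
  final_obj <- sum(shape_project(theta, Pall[, 1:2, drop = FALSE],
                                 n_poly)$distance^2)
  structure(list(transform = rigid_transform(R, tvec),
                 mean_shape = as_shape_params(theta),
                 objective = final_obj, iterations = iterations,
                 converged = converged),
            class = "vessel_frame")
}

#' @export
print.vessel_frame <- function(x, ...) {
  cat(sprintf("Vessel coordinate frame (%d alternating iterations%s)\n",
              x$iterations, if (x$converged) "" else ", not converged"))
  cat(sprintf("  objective (sum sq. dist): %.4g um^2\n", x$objective))
  cat("  mean shape: ")
  print(x$mean_shape)
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Fit a single cross-sectional shape to 2D points by (weighted) least
# squares on polygon-projection distances. Used for the mean shape (squared
# distances, unit weights).
fit_mean_shape <- function(xy, init = NULL, n_poly = 360L) {
  if (is.null(init)) {
    m0 <- colMeans(xy)
    r0 <- stats::median(sqrt(rowSums(sweep(xy, 2L, m0)^2)))
    init <- shape_params(m0[1], m0[2], r0, r0, r0, 1, 1)
  }
  lower <- c(-Inf, -Inf, 0.2, 0.2, 0.2, shape_exponent_bounds[1],
             shape_exponent_bounds[1])
  upper <- c(Inf, Inf, Inf, Inf, Inf, shape_exponent_bounds[2],
             shape_exponent_bounds[2])
  scale0 <- max(init[["a"]], init[["b"]], init[["c"]])
  w1 <- rep(1, nrow(xy))
  n_poly_opt <- max(90L, n_poly %/% 4L)
  mk_fn <- function(np) function(par)
    .shape_objective_cpp(pmin(pmax(par, lower), upper), xy, w1, np, TRUE)
  ctl <- list(maxit = 60, factr = 1e7,
              parscale = c(scale0, scale0, scale0, scale0, scale0, 1, 1))
  res <- stats::optim(as.numeric(init), mk_fn(n_poly_opt),
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = ctl)
  res <- stats::optim(res$par, mk_fn(n_poly), method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = utils::modifyList(ctl, list(maxit = 20)))
  as_shape_params(pmin(pmax(res$par, lower), upper))
}
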