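#' Tuning parameters for vessel reconstruction
#'
#' Collects the 13 tuning parameters of the reconstruction pipeline plus the
#' exclusion-filter thresholds. Precision parameters (`M_rel`, `n_poly`,
#' `n_cross_rel`, `n_interp_rel`, `eps_spline`, `n_spline_rel`) control how
#' densely contours and surfaces are discretised; data-complexity parameters
#' (`r`, `dh`) control contour enrichment; local-estimation-quality
#' parameters (`n_oct`, `lambda`, `sigma`, with truncation factors `Z_omega`,
#' `Z_sigma`) balance locality, plausibility and smoothness of the estimated
#' cross-sections.
#'
#' @param r enrichment cylinder radius (um).
#' @param dh enrichment cylinder length extension (um).
#' @param n_interp_rel interpolated points per um of contour edge.
#' @param eps_spline smoothing-spline mean squared residual bound (um^2).
#' @param n_spline_rel equidistant spline samples per um of arc length.
#' @param M_rel cross-sections per um of vessel length.
#' @param n_poly polygon density for shape projections.
#' @param n_cross_rel grid points per um of cross-section circumference.
#' @param Z_omega weight-function truncation, in units of `omega_k`.
#' @param Z_sigma smoothing-kernel truncation, in units of `sigma`.
#' @param n_oct minimum points with non-zero weight per plane octant.
#' @param lambda maximum allowed deviation (`dev_cross`) of a local
#'   cross-section from the mean shape (fraction).
#' @param sigma standard deviation (um) of the Gaussian filter applied to
#'   shape parameters along the axis.
#' @param squared_residuals if `TRUE`, minimise weighted squared projection
#'   distances in the per-plane fit instead of the default weighted sum of
#'   (unsquared) distances.
#' @param max_projection_distance cell exclusion threshold (um) on the
#'   annotated-vs-projected contour distance.
#' @param min_cells_per_plane,plane_cell_radius cross-section exclusion: keep
#'   a plane only if at least `min_cells_per_plane` annotated cells have a
#'   point within `plane_cell_radius` um of it.
#' @return A list of class `vessel_control`.
#' @export
vessel_control <- function(r = 1, dh = 1, n_interp_rel = 2, eps_spline = 0.1,
                           n_spline_rel = 2, M_rel = 2, n_poly = 360L,
                           n_cross_rel = 2, Z_omega = 2, Z_sigma = 2,
                           n_oct = 30L, lambda = 0.20, sigma = 10,
                           squared_residuals = FALSE,
                           max_projection_distance = 0.742,
                           min_cells_per_plane = 2L, plane_cell_radius = 0.5) {
  ctl <- list(r = r, dh = dh, n_interp_rel = n_interp_rel,
              eps_spline = eps_spline, n_spline_rel = n_spline_rel,
              M_rel = M_rel, n_poly = as.integer(n_poly),
              n_cross_rel = n_cross_rel, Z_omega = Z_omega, Z_sigma = Z_sigma,
              n_oct = as.integer(n_oct), lambda = lambda, sigma = sigma,
              squared_residuals = isTRUE(squared_residuals),
              max_projection_distance = max_projection_distance,
              min_cells_per_plane = as.integer(min_cells_per_plane),
              plane_cell_radius = plane_cell_radius)
  num <- unlist(ctl[c("r", "dh", "eps_spline", "n_spline_rel", "M_rel",
                      "n_poly", "n_cross_rel", "Z_omega", "Z_sigma", "n_oct",
                      "max_projection_distance", "plane_cell_radius")])
  if (any(num <= 0)) stop("tuning parameters must be positive", call. = FALSE)
  if (ctl$lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (ctl$sigma < 0) stop("sigma must be >= 0 (0 disables smoothing)",
                          call. = FALSE)
  if (ctl$n_interp_rel < 0) stop("n_interp_rel must be >= 0", call. = FALSE)
  if (ctl$n_oct < 1L) stop("n_oct must be >= 1", call. = FALSE)
  class(ctl) <- "vessel_control"
  ctl
}

#' @export
print.vessel_control <- function(x, ...) {
  cat("Vessel reconstruction tuning parameters:\n")
  flat <- unlist(x[setdiff(names(x), "squared_residuals")])
  cat(paste0("  ", names(flat), " = ", format(flat, digits = 4),
             collapse = "\n"), "\n")
  cat("  squared_residuals =", x$squared_residuals, "\n")
  invisible(x)
}

#' Read/write a control file
#'
#' Plain `key = value` text files holding the tuning parameters, for use by
#' the command-line interface.
#'
#' @param path file path.
#' @return A [vessel_control()].
#' @export
read_control <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- stats::setNames(
    lapply(kv, function(p) {
      v <- trimws(p[2])
      if (v %in% c("TRUE", "FALSE")) as.logical(v) else as.numeric(v)
    }),
    vapply(kv, function(p) trimws(p[1]), character(1)))
  do.call(vessel_control, args)
}

#' @rdname read_control
#' @param control a [vessel_control()].
#' @export
write_control <- function(control, path) {
  vals <- vapply(control, function(v) format(v, digits = 12), character(1))
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}
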