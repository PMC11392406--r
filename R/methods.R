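#' @export
print.vessel_recon <- function(x, ...) {
  cm <- x$cell_measures
  cat("Contour-based vessel surface reconstruction\n")
  cat(sprintf("  dataset: %s (%d cells)\n", x$dataset$embryo_id,
              length(x$dataset$contours)))
  cat(sprintf("  %d cross-sections over %.1f um; %d cells meshed, %d kept after filtering\n",
              length(x$grid$rings), diff(range(x$plane_measures$z)),
              length(x$meshes), sum(cm$kept, na.rm = TRUE)))
  cat(sprintf("  median projection distance: %.3f um\n",
              stats::median(cm$projection_distance, na.rm = TRUE)))
  cat("  mean shape: ")
  print(x$frame$mean_shape)
  invisible(x)
}

#' Summarise a vessel reconstruction
#'
#' Medians and quartile coefficients of dispersion of the filtered vessel
#' geometry (luminal area, diameter) and cell morphology (surface area,
#' perimeter, compactness, elongation) measurements, plus the sector
#' classification tally.
#'
#' @param object a [vessel_recon()] fit.
#' @param ... unused.
#' @return A list of class `summary.vessel_recon`.
#' @export
summary.vessel_recon <- function(object, ...) {
  cm <- object$cell_measures
  cmk <- cm[cm$kept & !is.na(cm$area), , drop = FALSE]
  pmk <- object$plane_measures[object$plane_measures$kept, , drop = FALSE]
  med_qcd <- function(v) {
    v <- v[!is.na(v)]
    c(median = stats::median(v),
      qcd = if (length(v) >= 4 && all(v > 0)) qcd(v)$qcd else NA_real_)
  }
  out <- list(
    embryo_id = object$dataset$embryo_id,
    n_cells = nrow(cm), n_cells_kept = nrow(cmk),
    n_planes = nrow(object$plane_measures), n_planes_kept = nrow(pmk),
    area_lum = med_qcd(pmk$area_lum),
    diam_lum = med_qcd(pmk$diam_lum),
    cell_area = med_qcd(cmk$area),
    cell_perim = med_qcd(cmk$perim),
    compact = med_qcd(cmk$compact),
    elong = med_qcd(cmk$elong),
    projection_distance = med_qcd(cm$projection_distance),
    classes = table(cmk$class),
    mean_shape = object$frame$mean_shape)
  class(out) <- "summary.vessel_recon"
  out
}

#' @export
print.summary.vessel_recon <- function(x, ...) {
  cat(sprintf("Vessel reconstruction summary (%s)\n", x$embryo_id))
  cat(sprintf("  cells: %d (%d kept); planes: %d (%d kept)\n", x$n_cells,
              x$n_cells_kept, x$n_planes, x$n_planes_kept))
  fmt <- function(nm, v, unit) {
    cat(sprintf("  %-22s median %9.3f %-5s QCD %5.1f%%\n", nm, v["median"],
                unit, 100 * v["qcd"]))
  }
  fmt("luminal area", x$area_lum, "um^2")
  fmt("luminal diameter", x$diam_lum, "um")
  fmt("cell surface area", x$cell_area, "um^2")
  fmt("cell perimeter", x$cell_perim, "um")
  fmt("compactness", x$compact, "")
  fmt("elongation", x$elong, "")
  cat(sprintf("  median projection distance: %.3f um\n",
              x$projection_distance["median"]))
  cat("  cell classes:", paste(names(x$classes), x$classes, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Shape parameters of a fitted vessel
#'
#' @param object a [vessel_recon()] fit.
#' @param type `"smooth"` (default) or `"raw"` per-plane parameters, or
#'   `"mean"` for the mean shape.
#' @param ... unused.
#' @return M x 7 matrix (with z as rownames) or a [shape_params()].
#' @export
coef.vessel_recon <- function(object, type = c("smooth", "raw", "mean"), ...) {
  type <- match.arg(type)
  if (type == "mean") return(object$frame$mean_shape)
  m <- switch(type, smooth = object$cross_sections$theta_smooth,
              raw = object$cross_sections$theta_raw)
  rownames(m) <- format(object$cross_sections$z, digits = 6)
  m
}

#' Predict cross-sections of a fitted vessel
#'
#' Interpolates the smoothed shape parameters at new axial positions and
#' optionally samples the predicted cross-section outline.
#'
#' @param object a [vessel_recon()] fit.
#' @param z axial positions (um, in vessel coordinates) inside the fitted
#'   range.
#' @param type `"params"` for shape parameters, `"ring"` for sampled
#'   outlines.
#' @param n_points points per predicted ring.
#' @param ... unused.
#' @return Matrix of parameters, or list of ring point matrices.
#' @export
predict.vessel_recon <- function(object, z, type = c("params", "ring"),
                                 n_points = 100L, ...) {
  type <- match.arg(type)
  zs <- object$cross_sections$z
  th <- object$cross_sections$theta_smooth
  ok <- stats::complete.cases(th)
  if (any(z < min(zs[ok]) | z > max(zs[ok])))
    stop("z outside the fitted range", call. = FALSE)
  out <- sapply(seq_len(ncol(th)), function(j)
    stats::approx(zs[ok], th[ok, j], xout = z, ties = "ordered")$y)
  out <- matrix(out, nrow = length(z),
                dimnames = list(format(z, digits = 6), colnames(th)))
  if (type == "params") return(out)
  lapply(seq_len(nrow(out)), function(i)
    cbind(shape_equidistant(as_shape_params(out[i, ]), n_k = n_points)$points,
          z = z[i]))
}

#' Residuals of a vessel reconstruction
#'
#' @param object a [vessel_recon()] fit.
#' @param type `"cells"`: per-cell symmetric contour distance between
#'   annotation and projection (the goodness-of-fit measure); `"planes"`:
#'   per-plane deviation of the smoothed shape from the mean shape.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.vessel_recon <- function(object, type = c("cells", "planes"), ...) {
  type <- match.arg(type)
  if (type == "cells") {
    r <- object$cell_measures$projection_distance
    names(r) <- object$cell_measures$cell_id
    return(r)
  }
  r <- object$cross_sections$dev_smooth
  names(r) <- format(object$cross_sections$z, digits = 6)
  r
}

#' Plot a vessel reconstruction
#'
#' `which = 1`: axial profiles of the smoothed shape parameters;
#' `which = 2`: cross-section outlines at selected planes with nearby
#' contour points; `which = 3`: per-cell projection distances.
#'
#' @param x a [vessel_recon()] fit.
#' @param which plots to draw.
#' @param ... unused.
#' @export
plot.vessel_recon <- function(x, which = 1L, ...) {
  cs <- x$cross_sections
  if (1L %in% which) {
    old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    graphics::matplot(cs$z, cs$theta_smooth[, c("a", "b", "c")], type = "l",
                      lty = 1, xlab = "z (um)", ylab = "semi-axis (um)",
                      main = "smoothed cross-section parameters")
    graphics::legend("topright", c("a (dorsal)", "b (ventral)", "c (lateral)"),
                     col = 1:3, lty = 1, bty = "n", cex = 0.8)
    graphics::matplot(cs$z, cs$theta_smooth[, c("alpha", "beta")], type = "l",
                      lty = 1, xlab = "z (um)", ylab = "exponent")
    graphics::legend("topright", c("alpha", "beta"), col = 1:2, lty = 1,
                     bty = "n", cex = 0.8)
  }
  if (2L %in% which) {
    ks <- unique(round(seq(1, length(x$grid$rings), length.out = 4)))
    old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    pts <- do.call(rbind, lapply(x$samples_transf, function(ct) ct$points))
    for (k in ks) {
      ring <- x$grid$rings[[k]]
      near <- abs(pts[, 3] - ring$z) < 2
      graphics::plot(ring$points[, 1:2], type = "l", asp = 1,
                     xlab = "x (um)", ylab = "y (um)",
                     main = sprintf("z = %.1f um", ring$z))
      if (any(near)) graphics::points(pts[near, 1:2], pch = 16, cex = 0.3,
                                      col = "grey50")
    }
  }
  if (3L %in% which) {
    r <- residuals.vessel_recon(x, "cells")
    graphics::barplot(r, las = 2, ylab = "projection distance (um)",
                      main = "per-cell goodness of fit")
    graphics::abline(h = x$control$max_projection_distance, lty = 2,
                     col = "red")
  }
  invisible(x)
}

#' Simulate datasets from a fitted vessel
#'
#' Uses the fitted smoothed parameter profile as the ground truth of a
#' synthetic tube and samples new annotated datasets from it, enabling
#' parametric-bootstrap style checks of the pipeline on vessels shaped like
#' the fitted one.
#'
#' @param object a [vessel_recon()] fit.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param n_cells,noise_sd generator settings; defaults: the fitted cell
#'   count and the median projection distance.
#' @param ... unused.
#' @return List of [simulate_vessel()] results (length `nsim`).
#' @export
simulate.vessel_recon <- function(object, nsim = 1, seed = 1L, n_cells = NULL,
                                  noise_sd = NULL, ...) {
  cs <- object$cross_sections
  ok <- stats::complete.cases(cs$theta_smooth)
  zs <- cs$z[ok] - min(cs$z[ok])
  th <- cs$theta_smooth[ok, , drop = FALSE]
  fns <- lapply(seq_len(ncol(th)), function(j)
    stats::approxfun(zs, th[, j], rule = 2))
  theta_fn <- function(z) {
    v <- vapply(fns, function(f) f(z), numeric(1))
    names(v) <- colnames(th)
    v
  }
  if (is.null(n_cells)) n_cells <- max(2L, length(object$dataset$contours))
  if (is.null(noise_sd))
    noise_sd <- stats::median(object$cell_measures$projection_distance,
                              na.rm = TRUE) / 2
  lapply(seq_len(nsim), function(i)
    simulate_vessel(tube_spec(length = max(zs), n_cells = n_cells,
                              noise_sd = noise_sd, theta_fn = theta_fn,
                              seed = seed + i - 1L)))
}
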