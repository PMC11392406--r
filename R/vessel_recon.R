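#' Reconstruct a vessel surface from cell contours
#'
#' The package's main fitting function. From a dataset of annotated
#' endothelial cell contours it (1) enriches, interpolates and smooths the
#' contours into periodic splines, (2) estimates the vessel-intrinsic
#' coordinate frame and mean cross-sectional shape, (3) fits a constrained
#' weighted superellipse cross-section at equidistant planes along the axis,
#' smooths the parameters and samples the organized surface grid, (4)
#' projects every cell contour onto the grid and triangulates per-cell
#' surface meshes, and (5) quantifies vessel geometry and 3D cell
#' morphology, applying the projection-distance cell filter and the
#' annotation-density cross-section filter before reporting.
#'
#' @param dataset a [contour_dataset()].
#' @param control a [vessel_control()].
#' @param verbose print per-stage progress.
#' @return An object of class `vessel_recon`; see [summary.vessel_recon()],
#'   [coef.vessel_recon()], [predict.vessel_recon()],
#'   [residuals.vessel_recon()], [plot.vessel_recon()].
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_vessel(tube_spec(length = 40, n_cells = 10, seed = 7))
#' fit <- vessel_recon(sim$dataset, vessel_control(M_rel = 1))
#' print(fit)
#' }
vessel_recon <- function(dataset, control = vessel_control(),
                         verbose = FALSE) {
  cl <- match.call()
  if (verbose) message("preprocessing contours ...")
  prep <- preprocess_contours(dataset, control)
  if (verbose) message("estimating coordinate frame and mean shape ...")
  frame <- estimate_frame(prep$samples, dataset$axes)
  fit <- vessel_recon_fit(dataset, prep, frame, control, verbose = verbose)
  fit$call <- cl
  fit
}

# Everything downstream of the frame; reused by sensitivity_scan() so the
# preprocessing and frame are shared across re-estimations.
vessel_recon_fit <- function(dataset, prep, frame, control, verbose = FALSE) {
  T <- frame$transform
  samples_transf <- lapply(prep$samples, function(ct)
    vessel_contour(ct$cell_id, apply_transform(T, ct$points), "transf",
                   u = ct$u))
  splines_transf <- lapply(prep$splines, transform_spline, transform = T)
  anno_transf <- lapply(dataset$contours, function(ct)
    vessel_contour(ct$cell_id, apply_transform(T, ct$points), "transf"))
  points <- do.call(rbind, lapply(samples_transf, function(ct) ct$points))

  if (verbose) message("estimating cross-sections ...")
  cs <- estimate_cross_sections(points, frame$mean_shape, control)
  grid <- cs$grid

  if (verbose) message("projecting and triangulating cells ...")
  ids <- names(dataset$contours)
  projections <- list(); meshes <- list()
  excluded_cells <- data.frame(cell_id = character(0), reason = character(0))
  for (id in ids) {
    proj <- tryCatch(project_contour_to_grid(splines_transf[[id]], grid),
                     error = function(e) e)
    if (inherits(proj, "error")) {
      excluded_cells <- rbind(excluded_cells,
                              data.frame(cell_id = id,
                                         reason = conditionMessage(proj)))
      next
    }
    mesh <- tryCatch(triangulate_cell(proj, grid), error = function(e) e)
    if (inherits(mesh, "error")) {
      excluded_cells <- rbind(excluded_cells,
                              data.frame(cell_id = id,
                                         reason = conditionMessage(mesh)))
      next
    }
    projections[[id]] <- proj
    meshes[[id]] <- mesh
  }

  if (verbose) message("measuring ...")
  cellm <- measure_cells(ids, projections, meshes, anno_transf, grid)
  cfil <- filter_cells(cellm, control$max_projection_distance)
  cellm$kept <- cellm$cell_id %in% cfil$kept$cell_id

  planem <- measure_planes(grid, anno_transf, control)

  manifest <- list(
    package = "lumenfit",
    version = as.character(utils::packageVersion("lumenfit")),
    embryo_id = dataset$embryo_id,
    control = unclass(control),
    n_cells_input = length(dataset$contours),
    n_cells_meshed = length(meshes),
    n_planes = length(cs$z),
    skipped_planes = cs$skipped,
    non_converged_planes = which(!cs$converged),
    failed_cells = excluded_cells,
    cells_excluded_by_distance =
      cellm$cell_id[!cellm$kept & !is.na(cellm$projection_distance)],
    planes_excluded_by_density = planem$k[!planem$kept])

  structure(list(call = NULL, dataset = dataset, control = control,
                 prep = prep, frame = frame, cross_sections = cs,
                 grid = grid, samples_transf = samples_transf,
                 splines_transf = splines_transf, anno_transf = anno_transf,
                 projections = projections, meshes = meshes,
                 cell_measures = cellm, plane_measures = planem,
                 manifest = manifest),
            class = "vessel_recon")
}

measure_cells <- function(ids, projections, meshes, anno_transf, grid) {
  rows <- lapply(ids, function(id) {
    base <- data.frame(cell_id = id, area = NA_real_, perim = NA_real_,
                       compact = NA_real_, elong = NA_real_,
                       frac_dorsal = NA_real_, frac_ventral = NA_real_,
                       frac_left = NA_real_, frac_right = NA_real_,
                       class = NA_character_, detailed = NA_character_,
                       projection_distance = NA_real_,
                       stringsAsFactors = FALSE)
    mesh <- meshes[[id]]
    proj <- projections[[id]]
    if (is.null(mesh) || is.null(proj)) return(base)
    base$area <- cell_area(mesh)
    base$perim <- cell_perimeter(proj)
    base$compact <- suppressWarnings(compactness(base$area, base$perim))
    el <- tryCatch(elongation(mesh, grid), error = function(e) NULL)
    if (!is.null(el)) base$elong <- el$elong
    cls <- classify_cell(mesh, grid)
    base$frac_dorsal <- cls$fractions[["dorsal"]]
    base$frac_ventral <- cls$fractions[["ventral"]]
    base$frac_left <- cls$fractions[["left"]]
    base$frac_right <- cls$fractions[["right"]]
    base$class <- cls$class
    base$detailed <- cls$detailed
    base$projection_distance <-
      projection_distance(anno_transf[[id]], proj)
    base
  })
  do.call(rbind, rows)
}

measure_planes <- function(grid, anno_transf, control) {
  zs <- vapply(grid$rings, function(r) r$z, numeric(1))
  fil <- filter_cross_sections(zs, anno_transf, control$min_cells_per_plane,
                               control$plane_cell_radius)
  data.frame(k = seq_along(grid$rings), z = zs,
             area_lum = vapply(grid$rings, function(r)
               luminal_area(r, check = FALSE), numeric(1)),
             diam_lum = vapply(grid$rings, luminal_diameter, numeric(1)),
             n_nearby_cells = fil$n_nearby,
             kept = seq_along(grid$rings) %in% fil$kept)
}

#' Tabulate measurements in long form
#'
#' Converts a fit's (filtered) cell and plane measurements into the long
#' `embryo_id / timepoint / object_id / measure / value` table written by
#' [write_measures()].
#'
#' @param fit a [vessel_recon()] object.
#' @param filtered apply the exclusion filters (default `TRUE`).
#' @return data.frame in long form.
#' @export
measure_table <- function(fit, filtered = TRUE) {
  cm <- fit$cell_measures
  pm <- fit$plane_measures
  if (filtered) {
    cm <- cm[cm$kept & !is.na(cm$area), , drop = FALSE]
    pm <- pm[pm$kept, , drop = FALSE]
  }
  long <- function(df, idcol, cols, prefix) {
    do.call(rbind, lapply(cols, function(m)
      data.frame(embryo_id = fit$dataset$embryo_id,
                 timepoint = fit$dataset$timepoint,
                 object_id = paste0(prefix, df[[idcol]]),
                 measure = m, value = as.numeric(df[[m]]),
                 stringsAsFactors = FALSE)))
  }
  rbind(long(cm, "cell_id", c("area", "perim", "compact", "elong",
                              "projection_distance"), "cell_"),
        long(pm, "k", c("area_lum", "diam_lum"), "plane_"))
}

#' Sensitivity of the reconstruction to the estimation-quality parameters
#'
#' Re-estimates the vessel surface with `n_oct`, `lambda` and `sigma`
#' individually scaled by each factor (preprocessing and frame are shared
#' with the base run), and tabulates the deviation of each re-estimated
#' cross-section from its reference (`dev_cross`) plus the relative
#' deviation (`dev_rel`) of every morphometric and geometric measurement.
#'
#' @param dataset a [contour_dataset()].
#' @param control base [vessel_control()].
#' @param params which parameters to scan.
#' @param factors scale factors (a `sigma` factor of 0 disables smoothing).
#' @param base optionally a precomputed base [vessel_recon()] fit.
#' @return List of class `sensitivity_scan`: `base` fit, `runs` (per
#'   param/factor: fit, `plane_dev` vector, `measure_dev` data.frame),
#'   `summary` data.frame.
#' @export
sensitivity_scan <- function(dataset, control = vessel_control(),
                             params = c("n_oct", "lambda", "sigma"),
                             factors = c(0.5, 2), base = NULL) {
  if (is.null(base)) base <- vessel_recon(dataset, control)
  prep <- base$prep
  frame <- base$frame
  runs <- list()
  summ <- NULL
  for (par in params) {
    for (f in factors) {
      ctl <- base$control
      val <- if (par == "n_oct") max(1L, as.integer(round(ctl[[par]] * f)))
      else ctl[[par]] * f
      ctl[[par]] <- val
      alt <- vessel_recon_fit(dataset, prep, frame, ctl)
      pd <- plane_deviation(alt, base)
      md <- measure_deviation(alt, base)
      tag <- sprintf("%s_x%g", par, f)
      runs[[tag]] <- list(param = par, factor = f, value = val, fit = alt,
                          plane_dev = pd, measure_dev = md)
      summ <- rbind(summ, data.frame(
        param = par, factor = f, value = val,
        median_plane_dev = stats::median(pd, na.rm = TRUE),
        frac_planes_below_5pct = mean(pd < 0.05, na.rm = TRUE),
        max_abs_measure_dev = max(abs(md$dev_rel), na.rm = TRUE)))
    }
  }
  structure(list(base = base, runs = runs, summary = summ),
            class = "sensitivity_scan")
}

# dev_cross of each altered plane vs the same plane of the reference run.
plane_deviation <- function(alt, base) {
  za <- vapply(alt$grid$rings, function(r) r$z, numeric(1))
  zb <- vapply(base$grid$rings, function(r) r$z, numeric(1))
  common <- intersect(round(za, 9), round(zb, 9))
  vapply(common, function(z) {
    ia <- which(round(za, 9) == z)[1]
    ib <- which(round(zb, 9) == z)[1]
    dev_cross(alt$grid$rings[[ia]]$theta, base$grid$rings[[ib]]$theta)
  }, numeric(1))
}

measure_deviation <- function(alt, base) {
  out <- NULL
  am <- alt$cell_measures; bm <- base$cell_measures
  common <- intersect(am$cell_id[am$kept], bm$cell_id[bm$kept])
  for (m in c("area", "perim", "compact", "elong")) {
    a <- am[[m]][match(common, am$cell_id)]
    b <- bm[[m]][match(common, bm$cell_id)]
    ok <- !is.na(a) & !is.na(b) & a != 0
    out <- rbind(out, data.frame(object = paste0("cell_", common[ok]),
                                 measure = m, dev_rel = dev_rel(a[ok], b[ok])))
  }
  ap <- alt$plane_measures; bp <- base$plane_measures
  zc <- intersect(round(ap$z[ap$kept], 9), round(bp$z[bp$kept], 9))
  for (m in c("area_lum", "diam_lum")) {
    a <- ap[[m]][match(zc, round(ap$z, 9))]
    b <- bp[[m]][match(zc, round(bp$z, 9))]
    out <- rbind(out, data.frame(object = sprintf("plane_z%.3f", zc),
                                 measure = m, dev_rel = dev_rel(a, b)))
  }
  out
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat("Sensitivity scan (dev_cross vs base run per plane; dev_rel per measurement)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
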