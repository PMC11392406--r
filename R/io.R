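#' Construct a cell contour
#'
#' An ordered, closed sequence of 3D points (micrometres) outlining one
#' endothelial cell's junctions. The stored sequence never repeats the first
#' point at the end; downstream operations treat the successor of the last
#' point as the first. Contours may be annotated clockwise or
#' counter-clockwise; no orientation normalisation is applied.
#'
#' @param cell_id identifier (coerced to character).
#' @param points n x 3 numeric matrix, n >= 3, consecutive points distinct.
#' @param stage processing stage, one of `"anno"`, `"enri"`,
#'   `"spline_sample"`, `"transf"`, `"proj"`.
#' @param u optional per-point spline parameter values.
#' @return Object of class `vessel_contour`.
#' @export
vessel_contour <- function(cell_id, points, stage = "anno", u = NULL) {
  stage <- match.arg(stage, c("anno", "enri", "spline_sample", "transf", "proj"))
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L)
    stop("contour points must have 3 coordinates", call. = FALSE)
  if (!all(is.finite(points)))
    stop(sprintf("cell %s: non-finite coordinates", cell_id), call. = FALSE)
  if (nrow(points) < 3L)
    stop(sprintf("cell %s: a contour needs at least 3 points", cell_id),
         call. = FALSE)
  nxt <- c(2:nrow(points), 1L)
  gaps <- sqrt(rowSums((points[nxt, , drop = FALSE] - points)^2))
  if (any(gaps == 0))
    stop(sprintf("cell %s: consecutive contour points must be distinct", cell_id),
         call. = FALSE)
  structure(list(cell_id = as.character(cell_id), points = points,
                 stage = stage, u = u),
            class = "vessel_contour")
}

#' @export
print.vessel_contour <- function(x, ...) {
  cat(sprintf("Cell contour %s [%s]: %d points, perimeter %.2f um\n",
              x$cell_id, x$stage, nrow(x$points), contour_perimeter(x$points)))
  invisible(x)
}

contour_perimeter <- function(points) {
  nxt <- c(2:nrow(points), 1L)
  sum(sqrt(rowSums((points[nxt, , drop = FALSE] - points)^2)))
}

#' Construct an annotation dataset
#'
#' Bundles the cell contours of one vessel segment with the three manually
#' annotated axis vectors and optional angiogram slices.
#'
#' @param contours list of [vessel_contour()] objects with unique cell ids.
#' @param axes list with elements `ap`, `dv`, `lr`, each a 2 x 3 matrix of two
#'   ordered points giving the approximate anterior-posterior, dorsal-ventral
#'   (as annotated) and left-right directions.
#' @param embryo_id,phenotype,timepoint free-form metadata (timepoint in hpf).
#' @param slices optional list of planar closed point sequences (n x 3
#'   matrices), e.g. annotated angiogram slices.
#' @return Object of class `contour_dataset`.
#' @export
contour_dataset <- function(contours, axes, embryo_id = "synthetic",
                            phenotype = "wt", timepoint = NA_real_,
                            slices = NULL) {
  ids <- vapply(contours, function(ct) ct$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("cell ids must be unique within a dataset", call. = FALSE)
  names(contours) <- ids
  for (nm in c("ap", "dv", "lr")) {
    v <- axes[[nm]]
    if (is.null(v) || !all(dim(as.matrix(v)) == c(2L, 3L)))
      stop(sprintf("axis '%s' must be a 2 x 3 matrix of two points", nm),
           call. = FALSE)
    if (sum((v[2, ] - v[1, ])^2) == 0)
      stop(sprintf("axis '%s': the two points must be distinct", nm),
           call. = FALSE)
    v <- as.matrix(v)
    dimnames(v) <- NULL
    axes[[nm]] <- v
  }
  structure(list(embryo_id = embryo_id, phenotype = phenotype,
                 timepoint = timepoint, contours = contours,
                 axes = axes[c("ap", "dv", "lr")], slices = slices),
            class = "contour_dataset")
}

#' @export
print.contour_dataset <- function(x, ...) {
  npts <- sum(vapply(x$contours, function(ct) nrow(ct$points), integer(1)))
  cat(sprintf("Contour dataset '%s' (%s, %s hpf): %d cells, %d points\n",
              x$embryo_id, x$phenotype, format(x$timepoint), length(x$contours),
              npts))
  if (!is.null(x$slices))
    cat(sprintf("  plus %d angiogram slices\n", length(x$slices)))
  invisible(x)
}

axis_row_ids <- c(ap = "axis_ap", dv = "axis_dv", lr = "axis_lr")

#' Read contour annotations from CSV
#'
#' Expects comma-separated values with a header and columns `cell_id`,
#' `point_index`, `x`, `y`, `z` (coordinates in micrometres), one point per
#' row. Axis vectors are stored in the same file as two-point rows with
#' `cell_id` equal to `axis_ap`, `axis_dv`, `axis_lr`.
#'
#' @param path CSV file path.
#' @param embryo_id,phenotype,timepoint metadata attached to the dataset.
#' @return A [contour_dataset()].
#' @export
read_contours <- function(path, embryo_id = basename(path), phenotype = "wt",
                          timepoint = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "point_index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  df$cell_id <- as.character(df$cell_id)
  is_axis <- df$cell_id %in% axis_row_ids
  axes <- list()
  for (nm in names(axis_row_ids)) {
    rows <- df[df$cell_id == axis_row_ids[[nm]], , drop = FALSE]
    if (nrow(rows) != 2L)
      stop(sprintf("axis '%s' must have exactly 2 rows", axis_row_ids[[nm]]),
           call. = FALSE)
    rows <- rows[order(rows$point_index), , drop = FALSE]
    axes[[nm]] <- as.matrix(rows[, c("x", "y", "z")])
  }
  cells <- df[!is_axis, , drop = FALSE]
  contours <- lapply(split(cells, cells$cell_id), function(d) {
    d <- d[order(d$point_index), , drop = FALSE]
    vessel_contour(d$cell_id[1], as.matrix(d[, c("x", "y", "z")]), "anno")
  })
  # preserve first-appearance order of cells in the file
  contours <- contours[unique(cells$cell_id)]
  contour_dataset(contours, axes, embryo_id = embryo_id,
                  phenotype = phenotype, timepoint = timepoint)
}

#' Write contour annotations to CSV
#'
#' Inverse of [read_contours()]; coordinates are written with 12 significant
#' digits so that a read/write round trip is exact to well below annotation
#' resolution.
#'
#' @param dataset a [contour_dataset()].
#' @param path output CSV path.
#' @export
write_contours <- function(dataset, path) {
  rows <- lapply(dataset$contours, function(ct) {
    data.frame(cell_id = ct$cell_id, point_index = seq_len(nrow(ct$points)),
               x = ct$points[, 1], y = ct$points[, 2], z = ct$points[, 3])
  })
  for (nm in names(axis_row_ids)) {
    v <- dataset$axes[[nm]]
    rows[[axis_row_ids[[nm]]]] <-
      data.frame(cell_id = axis_row_ids[[nm]], point_index = 1:2,
                 x = v[, 1], y = v[, 2], z = v[, 3])
  }
  df <- do.call(rbind, rows)
  df$x <- formatC(df$x, digits = 12, format = "g")
  df$y <- formatC(df$y, digits = 12, format = "g")
  df$z <- formatC(df$z, digits = 12, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read angiogram slices from CSV
#'
#' Columns `slice_id`, `point_index`, `x`, `y`, `z`; each slice an ordered
#' closed planar point sequence in micrometres.
#'
#' @param path CSV file path.
#' @return Named list of n x 3 matrices.
#' @export
read_angiogram_slices <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_id", "point_index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$slice_id), function(d) {
    d <- d[order(d$point_index), , drop = FALSE]
    as.matrix(d[, c("x", "y", "z")])
  })
  out[unique(as.character(df$slice_id))]
}

#' Write a measurement table to CSV
#'
#' Rows carry embryo id, timepoint, the measured object's id, the measure
#' name and its value. String fields round-trip bit-identically; numeric
#' values are written with 12 significant digits.
#'
#' @param table data.frame with columns `embryo_id`, `timepoint`,
#'   `object_id`, `measure`, `value`.
#' @param path output CSV path.
#' @export
write_measures <- function(table, path) {
  need <- c("embryo_id", "timepoint", "object_id", "measure", "value")
  if (!all(need %in% names(table)))
    stop("measure table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  table <- table[, need, drop = FALSE]
  table$value <- formatC(table$value, digits = 12, format = "g")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_measures()]
#'
#' @param path CSV file path.
#' @return data.frame with the five standard columns.
#' @export
read_measures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(embryo_id = "character",
                                       object_id = "character",
                                       measure = "character"))
  df
}

#' Export a triangle mesh as a legacy VTK polydata file
#'
#' Writes an ASCII VTK file readable by standard viewers (e.g. Paraview).
#'
#' @param vertices n x 3 matrix of vertex coordinates.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param path output `.vtk` path.
#' @param name dataset name written into the header.
#' @export
write_vtk_polydata <- function(vertices, triangles, path, name = "lumenfit mesh") {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(vertices))), con)
  utils::write.table(format(vertices, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(triangles), 4L * nrow(triangles)),
             con)
  utils::write.table(cbind(3L, triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
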