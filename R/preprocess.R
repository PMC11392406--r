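#' Enrich cell contours with points of neighbouring cells
#'
#' Because each cell is annotated independently, joint cell-cell contacts are
#' annotated twice. Enrichment inserts, into each cell's contour, those points
#' of other cells' annotated contours that lie within a cylinder of radius `r`
#' and length `||p+ - p|| + 2 * dh` centred on an edge `(p, p+)` of the
#' current (growing) enriched contour. If a point lies inside at least one
#' cylinder without the length extension, it is inserted into the edge with
#' minimal orthogonal distance; if it lies only inside cylinder extensions
#' (near a sharp bend), it is inserted adjacent to its nearest contour point,
#' on the side of the nearer of that point's two neighbours. Foreign points
#' are visited in a fixed order (ascending cell id, then point index) so the
#' result is reproducible; original points are never removed or reordered.
#'
#' @param dataset a [contour_dataset()] with all contours in one frame.
#' @param r cylinder radius (um), > 0.
#' @param dh cylinder length extension (um), > 0.
#' @return The dataset with contours at stage `"enri"`.
#' @export
enrich_contours <- function(dataset, r = 1, dh = 1) {
  stopifnot(r > 0, dh > 0)
  ids <- names(dataset$contours)
  ord <- order_cell_ids(ids)
  foreign <- do.call(rbind, lapply(dataset$contours[ord], function(ct) ct$points))
  foreign_cell <- rep(ids[ord], vapply(dataset$contours[ord],
                                       function(ct) nrow(ct$points), integer(1)))
  out <- dataset
  for (id in ids) {
    pts <- dataset$contours[[id]]$points
    sel <- foreign_cell != id
    qs <- foreign[sel, , drop = FALSE]
    for (qi in seq_len(nrow(qs))) {
      q <- qs[qi, ]
      # duplicate guard
      if (min(colSums((t(pts) - q)^2)) < 1e-18) next
      res <- .enrich_query_cpp(q, pts, r, dh)
      if (res[1] < 1) next         # outside all cylinders
      if (res[2] >= 1) {
        at <- res[3]               # insert inside edge (at, at+1)
      } else {
        v <- res[4]                # extension only: adjacent to nearest vertex
        n <- nrow(pts)
        prev <- if (v == 1) n else v - 1
        nxt <- if (v == n) 1 else v + 1
        d_prev <- sum((pts[prev, ] - q)^2)
        d_next <- sum((pts[nxt, ] - q)^2)
        at <- if (d_prev <= d_next) (if (v == 1) n else v - 1) else v
      }
      pts <- rbind(pts[seq_len(at), , drop = FALSE], q,
                   if (at < nrow(pts)) pts[(at + 1):nrow(pts), , drop = FALSE])
    }
    out$contours[[id]] <- vessel_contour(id, pts, "enri")
  }
  out
}

# Ascending cell-id order; numeric-aware when all ids are numbers.
order_cell_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids)
}

#' Interpolate additional points on contour edges
#'
#' Inserts `floor(n_interp_rel * ||p+ - p||)` equally spaced points on each
#' edge by linear interpolation, homogenising the point density along the
#' contour.
#'
#' @param contour a [vessel_contour()].
#' @param n_interp_rel interpolated points per micrometre of edge length
#'   (>= 0).
#' @return The contour with interpolated points (same stage).
#' @export
interpolate_contour <- function(contour, n_interp_rel = 2) {
  stopifnot(n_interp_rel >= 0)
  pts <- contour$points
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]; p2 <- pts[nxt[i], ]
    len <- sqrt(sum((p2 - p)^2))
    k <- floor(n_interp_rel * len)
    if (k > 0) {
      fr <- seq_len(k) / (k + 1)
      out[[i]] <- rbind(p, outer(1 - fr, p) + outer(fr, p2))
    } else out[[i]] <- matrix(p, nrow = 1)
  }
  vessel_contour(contour$cell_id, do.call(rbind, out), contour$stage)
}

#' Fit a periodic cubic smoothing spline to a closed contour
#'
#' Fits a closed 3D curve `s : [0, 1] -> R^3` with continuous first and
#' second derivatives through the contour, parameterised by the normalised
#' cumulative chord (arc) length of the input points. The curve is a
#' penalised cyclic cubic spline; the smoothing parameter is chosen by
#' bisection as the largest value (smoothest curve) for which the sum of
#' squared residuals stays below `eps_spline * n`, so `eps_spline` bounds the
#' mean squared distance from the points to the curve.
#'
#' @param contour a [vessel_contour()] with at least 4 distinct points.
#' @param eps_spline per-point residual budget (um^2).
#' @param k basis dimension; defaults to a resolution close to the data size.
#' @return Object of class `periodic_spline`.
#' @export
fit_periodic_spline <- function(contour, eps_spline = 0.1, k = NULL) {
  pts <- contour$points
  n <- nrow(pts)
  if (n < 4L) stop(sprintf("cell %s: need >= 4 points for a spline",
                           contour$cell_id), call. = FALSE)
  sv <- svd(sweep(pts, 2L, colMeans(pts)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop(sprintf("cell %s: degenerate (collinear) contour", contour$cell_id),
         call. = FALSE)
  nxt <- c(2:n, 1L)
  seg <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
  per <- sum(seg)
  if (per <= 0) stop(sprintf("cell %s: zero-length contour", contour$cell_id),
                     call. = FALSE)
  tpar <- c(0, cumsum(seg[-n])) / per
  if (is.null(k)) k <- max(10L, min(n, 220L))
  center <- colMeans(pts)
  y <- sweep(pts, 2L, center)
  budget <- eps_spline * n
  repeat {
    sm <- mgcv::smoothCon(mgcv::s(tpar, bs = "cc", k = k),
                          data = data.frame(tpar = tpar),
                          knots = list(tpar = seq(0, 1, length.out = k)),
                          absorb.cons = FALSE)[[1]]
    X <- sm$X
    S <- sm$S[[1]]
    XtX <- crossprod(X)
    Xty <- crossprod(X, y)
    fit_at <- function(lam) {
      b <- solve(XtX + lam * S + 1e-10 * diag(ncol(X)), Xty)
      r <- y - X %*% b
      list(coef = b, ssr = sum(r^2))
    }
    f0 <- fit_at(0)
    if (f0$ssr <= budget || k >= n) break
    k <- min(n, 2L * k)  # basis too coarse for the residual budget
  }
  lam <- 0
  if (f0$ssr > budget) {
    fit <- f0
  } else {
    hi <- 1
    while (fit_at(hi)$ssr <= budget && hi < 1e12) hi <- hi * 10
    if (fit_at(hi)$ssr <= budget) {
      lam <- hi
    } else {
      lo <- hi / 10
      while (fit_at(lo)$ssr > budget && lo > 1e-12) lo <- lo / 10
      for (it in 1:60) {
        mid <- sqrt(lo * hi)
        if (fit_at(mid)$ssr <= budget) lo <- mid else hi <- mid
      }
      lam <- lo
    }
    fit <- fit_at(lam)
  }
  structure(list(cell_id = contour$cell_id, sm = sm, coef = fit$coef,
                 center = center, n_src = n, ssr = fit$ssr, lambda = lam,
                 perimeter_chord = per),
            class = "periodic_spline")
}

#' Evaluate a periodic spline
#'
#' @param object a `periodic_spline`.
#' @param u parameter values; evaluated modulo 1.
#' @param ... unused.
#' @return n x 3 matrix of curve points.
#' @export
predict.periodic_spline <- function(object, u, ...) {
  u <- as.numeric(u) %% 1
  X <- mgcv::PredictMat(object$sm, data.frame(tpar = u))
  sweep(X %*% object$coef, 2L, object$center, "+")
}

#' @export
print.periodic_spline <- function(x, ...) {
  cat(sprintf("Periodic cubic smoothing spline (cell %s): %d source points, SSR %.4g um^2\n",
              x$cell_id, x$n_src, x$ssr))
  invisible(x)
}

# Apply a rigid transform to a periodic spline (curves are affine in the
# coefficients, so this is exact).
transform_spline <- function(spline, transform) {
  spline$coef <- spline$coef %*% t(transform$rotation)
  spline$center <- as.numeric(transform$rotation %*% spline$center) +
    transform$translation
  spline
}

# Dense arc-length table of a periodic spline.
spline_arc_table <- function(spline, n_dense = 4096L) {
  u <- seq(0, 1, length.out = n_dense + 1L)
  pts <- predict(spline, u)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-(n_dense + 1L), , drop = FALSE])^2))
  list(u = u, pts = pts, cum = c(0, cumsum(seg)))
}

#' Arc length of a periodic spline
#'
#' Total arc length, by dense chord summation (relative error well below
#' 1e-6 at the default density).
#'
#' @param spline a `periodic_spline`.
#' @param n_dense chord density.
#' @return Length in micrometres.
#' @export
spline_arclength <- function(spline, n_dense = 4096L) {
  tab <- spline_arc_table(spline, n_dense)
  tab$cum[length(tab$cum)]
}

#' Resample a spline into equidistant points
#'
#' Computes `floor(n_spline_rel * arclength)` points equally spaced in arc
#' length along the spline, the first at parameter 0.
#'
#' @param spline a `periodic_spline`.
#' @param n_spline_rel points per micrometre of arc length.
#' @return A [vessel_contour()] at stage `"spline_sample"` carrying the
#'   per-point parameter values in `$u`.
#' @export
resample_spline <- function(spline, n_spline_rel = 2) {
  tab <- spline_arc_table(spline)
  L <- tab$cum[length(tab$cum)]
  n_s <- floor(n_spline_rel * L)
  if (n_s < 3L)
    stop(sprintf("cell %s: spline resolution too low (n_spline < 3)",
                 spline$cell_id), call. = FALSE)
  targets <- (seq_len(n_s) - 1L) / n_s * L
  u <- stats::approx(tab$cum, tab$u, xout = targets, ties = "ordered")$y
  u[1] <- 0
  vessel_contour(spline$cell_id, predict(spline, u), "spline_sample", u = u)
}

#' Preprocess all contours of a dataset
#'
#' Convenience wrapper running neighbour enrichment, edge interpolation,
#' periodic smoothing-spline fitting and equidistant resampling for every
#' cell.
#'
#' @param dataset a [contour_dataset()].
#' @param control a [vessel_control()] supplying `r`, `dh`, `n_interp_rel`,
#'   `eps_spline` and `n_spline_rel`.
#' @return List with `splines` (named list of `periodic_spline`) and
#'   `samples` (named list of stage-`"spline_sample"` contours).
#' @export
preprocess_contours <- function(dataset, control = vessel_control()) {
  enriched <- enrich_contours(dataset, r = control$r, dh = control$dh)
  splines <- list()
  samples <- list()
  for (id in names(enriched$contours)) {
    ct <- interpolate_contour(enriched$contours[[id]], control$n_interp_rel)
    sp <- fit_periodic_spline(ct, eps_spline = control$eps_spline)
    splines[[id]] <- sp
    samples[[id]] <- resample_spline(sp, control$n_spline_rel)
  }
  list(splines = splines, samples = samples, enriched = enriched)
}
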