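#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Squared distance from point (px,py) to segment (ax,ay)-(bx,by); also
// returns the clamped projection parameter and the foot point via refs.
static inline double seg_dist2(double px, double py, double ax, double ay,
                               double bx, double by, double &fx, double &fy) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  fx = ax + t * dx;
  fy = ay + t * dy;
  double ex = px - fx, ey = py - fy;
  return ex * ex + ey * ey;
}

// Project 2D points onto a closed polygon (vertices in order, not repeated).
// Returns matrix [dist, foot_x, foot_y, edge_index(1-based)].
// [[Rcpp::export(name = ".proj_polygon_cpp")]]
NumericMatrix proj_polygon_cpp(NumericMatrix pts, NumericMatrix poly,
                               bool closed = true) {
  int n = pts.nrow(), m = poly.nrow();
  int nedge = closed ? m : (m - 1);
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf, bfx = NA_REAL, bfy = NA_REAL;
    int bedge = 0;
    for (int j = 0; j < nedge; ++j) {
      int j2 = (j + 1) % m;
      double fx, fy;
      double d2 = seg_dist2(px, py, poly(j, 0), poly(j, 1), poly(j2, 0),
                            poly(j2, 1), fx, fy);
      if (d2 < best) { best = d2; bfx = fx; bfy = fy; bedge = j + 1; }
    }
    out(i, 0) = std::sqrt(best);
    out(i, 1) = bfx;
    out(i, 2) = bfy;
    out(i, 3) = bedge;
  }
  return out;
}

// Minimal distances from 3D points to the segments of a 3D polyline
// (closed if closed = true). Returns vector of distances.
// [[Rcpp::export(name = ".dist_polyline3_cpp")]]
NumericVector dist_polyline3_cpp(NumericMatrix pts, NumericMatrix line,
                                 bool closed = true) {
  int n = pts.nrow(), m = line.nrow();
  int nedge = closed ? m : (m - 1);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nedge; ++j) {
      int j2 = (j + 1) % m;
      double ax = line(j, 0), ay = line(j, 1), az = line(j, 2);
      double dx = line(j2, 0) - ax, dy = line(j2, 1) - ay, dz = line(j2, 2) - az;
      double L2 = dx * dx + dy * dy + dz * dz;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / L2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      double ex = px - (ax + t * dx), ey = py - (ay + t * dy),
             ez = pz - (az + t * dz);
      double d2 = ex * ex + ey * ey + ez * ez;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Signed shoelace area of a polygon (vertices in order, not repeated).
// [[Rcpp::export(name = ".polygon_area_signed_cpp")]]
double polygon_area_signed_cpp(NumericMatrix poly) {
  int m = poly.nrow();
  double s = 0.0;
  for (int j = 0; j < m; ++j) {
    int j2 = (j + 1) % m;
    s += poly(j, 0) * poly(j2, 1) - poly(j2, 0) * poly(j, 1);
  }
  return 0.5 * s;
}

// Sutherland-Hodgman clipping of subject polygon by a CONVEX clip polygon.
// Both as n x 2 matrices, vertices in counter-clockwise order for clip.
// Returns the clipped polygon (possibly 0 rows).
// [[Rcpp::export(name = ".clip_polygon_convex_cpp")]]
NumericMatrix clip_polygon_convex_cpp(NumericMatrix subject,
                                      NumericMatrix clip) {
  std::vector<double> sx, sy;
  for (int i = 0; i < subject.nrow(); ++i) {
    sx.push_back(subject(i, 0));
    sy.push_back(subject(i, 1));
  }
  int m = clip.nrow();
  for (int j = 0; j < m && !sx.empty(); ++j) {
    int j2 = (j + 1) % m;
    double ax = clip(j, 0), ay = clip(j, 1);
    double ex = clip(j2, 0) - ax, ey = clip(j2, 1) - ay;
    std::vector<double> nx, ny;
    int k = (int)sx.size();
    for (int i = 0; i < k; ++i) {
      int i2 = (i + 1) % k;
      double cx = sx[i], cy = sy[i], dxp = sx[i2], dyp = sy[i2];
      // inside = left of directed clip edge (CCW polygon)
      double c_in = ex * (cy - ay) - ey * (cx - ax);
      double d_in = ex * (dyp - ay) - ey * (dxp - ax);
      bool cin = c_in >= 0.0, din = d_in >= 0.0;
      if (cin) { nx.push_back(cx); ny.push_back(cy); }
      if (cin != din) {
        double t = c_in / (c_in - d_in);
        nx.push_back(cx + t * (dxp - cx));
        ny.push_back(cy + t * (dyp - cy));
      }
    }
    sx = nx; sy = ny;
  }
  NumericMatrix out((int)sx.size(), 2);
  for (int i = 0; i < (int)sx.size(); ++i) {
    out(i, 0) = sx[i];
    out(i, 1) = sy[i];
  }
  return out;
}

// Even-odd point-in-polygon test for many points.
// [[Rcpp::export(name = ".points_in_polygon_cpp")]]
LogicalVector points_in_polygon_cpp(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    bool inside = false;
    for (int j = 0, j2 = m - 1; j < m; j2 = j++) {
      double xj = poly(j, 0), yj = poly(j, 1);
      double xk = poly(j2, 0), yk = poly(j2, 1);
      if (((yj > py) != (yk > py)) &&
          (px < (xk - xj) * (py - yj) / (yk - yj) + xj))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}

// Evaluate the joined-half-superellipse at parameters u (mirrors the R
// implementation exactly; dorsal half for u in [0, pi]).
static inline void shape_eval_one(const double *th, double u, double &x,
                                  double &y) {
  double mx = th[0], my = th[1], a = th[2], b = th[3], c = th[4];
  double e = (u <= M_PI) ? th[5] : th[6];
  double cu = std::cos(u), su = std::sin(u);
  if (std::fabs(cu) < 1e-12) cu = 0.0;
  if (std::fabs(su) < 1e-12) su = 0.0;
  double sgn = (cu > 0) - (cu < 0);
  x = mx + c * sgn * std::pow(std::fabs(cu), e);
  if (u <= M_PI)
    y = my + a * std::pow(std::fabs(su), e);
  else
    y = my - b * std::pow(std::fabs(su), e);
}

// Polygon approximation with n_poly linearly spaced parameters in [0, 2pi).
// [[Rcpp::export(name = ".shape_polygon_cpp")]]
NumericMatrix shape_polygon_cpp(NumericVector theta, int n_poly) {
  NumericMatrix out(n_poly, 2);
  for (int i = 0; i < n_poly; ++i) {
    double u = 2.0 * M_PI * i / n_poly;
    double x, y;
    shape_eval_one(REAL(theta), u, x, y);
    out(i, 0) = x;
    out(i, 1) = y;
  }
  return out;
}

// Weighted sum of (optionally squared) distances of 2D points to the shape
// polygon; the workhorse of the per-plane and mean-shape fits.
// [[Rcpp::export(name = ".shape_objective_cpp")]]
double shape_objective_cpp(NumericVector theta, NumericMatrix xy,
                           NumericVector w, int n_poly, bool squared) {
  std::vector<double> px(n_poly), py(n_poly);
  for (int i = 0; i < n_poly; ++i) {
    double u = 2.0 * M_PI * i / n_poly;
    shape_eval_one(REAL(theta), u, px[i], py[i]);
  }
  int n = xy.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double qx = xy(i, 0), qy = xy(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < n_poly; ++j) {
      int j2 = (j + 1) % n_poly;
      double fx, fy;
      double d2 = seg_dist2(qx, qy, px[j], py[j], px[j2], py[j2], fx, fy);
      if (d2 < best) best = d2;
    }
    total += w[i] * (squared ? best : std::sqrt(best));
  }
  return total;
}

// Cylinder membership used during contour enrichment: for a query point q and
// the edges of a closed contour, report (a) whether q lies inside any cylinder
// of radius r and half-length extension dh around an edge, (b) whether it lies
// inside any cylinder with dh = 0, and (c) for the dh = 0 case the edge with
// minimal orthogonal distance, for the extension-only case the nearest vertex.
// Returns: [in_any, in_core, best_core_edge(1-based), nearest_vertex(1-based)]
// [[Rcpp::export(name = ".enrich_query_cpp")]]
NumericVector enrich_query_cpp(NumericVector q, NumericMatrix contour,
                               double r, double dh) {
  int m = contour.nrow();
  double qx = q[0], qy = q[1], qz = q[2];
  bool in_any = false, in_core = false;
  double best_core = R_PosInf;
  int best_edge = 0;
  double best_vert = R_PosInf;
  int near_vert = 0;
  double r2 = r * r;
  for (int j = 0; j < m; ++j) {
    int j2 = (j + 1) % m;
    double ax = contour(j, 0), ay = contour(j, 1), az = contour(j, 2);
    double dx = contour(j2, 0) - ax, dy = contour(j2, 1) - ay,
           dz = contour(j2, 2) - az;
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) continue;
    double ux = dx / L, uy = dy / L, uz = dz / L;
    double t = (qx - ax) * ux + (qy - ay) * uy + (qz - az) * uz; // axial coord
    double wx = qx - (ax + t * ux), wy = qy - (ay + t * uy),
           wz = qz - (az + t * uz);
    double rad2 = wx * wx + wy * wy + wz * wz; // orthogonal distance^2
    if (rad2 <= r2) {
      if (t >= -dh && t <= L + dh) in_any = true;
      if (t >= 0.0 && t <= L) {
        in_core = true;
        if (rad2 < best_core) { best_core = rad2; best_edge = j + 1; }
      }
    }
    // track nearest vertex
    double vx = qx - ax, vy = qy - ay, vz = qz - az;
    double v2 = vx * vx + vy * vy + vz * vz;
    if (v2 < best_vert) { best_vert = v2; near_vert = j + 1; }
  }
  return NumericVector::create((double)in_any, (double)in_core,
                               (double)best_edge, (double)near_vert);
}
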