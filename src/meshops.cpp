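#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Brute-force nearest-neighbour matching with distance / normal-compatibility
// caps.  Candidate set restricted by `mask` (e.g. to exclude crop-boundary
// vertices).  Ties broken by lowest candidate index (strict < comparison).
//
// queries:  Q x 3, qnormals: Q x 3 (unit; may be all-zero to disable filter)
// points:   P x 3, pnormals: P x 3
// mask:     length P logical, TRUE = usable candidate
// dcap:     maximum allowed distance (mm), <=0 disables
// mincos:   minimum allowed normal dot product, <= -1 disables
//
// Returns list(index = 1-based index or 0 if no compatible candidate,
//              dist  = distance to matched point, NA if none)
// [[Rcpp::export(name = ".nn_match_cpp")]]
List nn_match_cpp(NumericMatrix queries, NumericMatrix qnormals,
                  NumericMatrix points, NumericMatrix pnormals,
                  LogicalVector mask, double dcap, double mincos) {
  const int Q = queries.nrow(), P = points.nrow();
  IntegerVector idx(Q);
  NumericVector dist(Q);
  const bool use_norm = mincos > -1.0;
  const bool use_dcap = dcap > 0.0;
  const double dcap2 = dcap * dcap;
  // column pointers (matrices are column-major)
  const double *qx_ = REAL(queries), *qy_ = qx_ + Q, *qz_ = qy_ + Q;
  const double *nx_ = REAL(qnormals), *ny_ = nx_ + Q, *nz_ = ny_ + Q;
  const double *px_ = REAL(points), *py_ = px_ + P, *pz_ = py_ + P;
  const double *mx_ = REAL(pnormals), *my_ = mx_ + P, *mz_ = my_ + P;
  const int *msk = LOGICAL(mask);
  for (int i = 0; i < Q; ++i) {
    const double qx = qx_[i], qy = qy_[i], qz = qz_[i];
    const double nx = nx_[i], ny = ny_[i], nz = nz_[i];
    double best = DBL_MAX;
    int besti = 0;
    for (int j = 0; j < P; ++j) {
      const double dx = px_[j] - qx;
      const double dy = py_[j] - qy;
      const double dz = pz_[j] - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= best) continue;
      if (!msk[j]) continue;
      if (use_dcap && d2 > dcap2) continue;
      if (use_norm) {
        const double dot = nx * mx_[j] + ny * my_[j] + nz * mz_[j];
        if (dot < mincos) continue;
      }
      best = d2;
      besti = j + 1;
    }
    idx[i] = besti;
    dist[i] = besti > 0 ? std::sqrt(best) : NA_REAL;
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out, double *bary) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1; bary[1] = 0; bary[2] = 0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0; bary[1] = 1; bary[2] = 0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0; bary[1] = 0; bary[2] = 1;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// Closest point on a triangulated surface for each query point.
// vertices: V x 3, faces: F x 3 (1-based), queries: Q x 3.
// Returns list(point = Q x 3, face = 1-based face index, dist, bary = Q x 3).
// [[Rcpp::export(name = ".closest_point_cpp")]]
List closest_point_cpp(NumericMatrix queries, NumericMatrix vertices,
                       IntegerMatrix faces) {
  const int Q = queries.nrow(), F = faces.nrow();
  NumericMatrix pts(Q, 3), bmat(Q, 3);
  IntegerVector fidx(Q);
  NumericVector dist(Q);
  // Precompute face centroids + circumradius-style bound for pruning.
  std::vector<double> cx(F), cy(F), cz(F), rad(F);
  for (int f = 0; f < F; ++f) {
    const int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    double gx = (vertices(ia, 0) + vertices(ib, 0) + vertices(ic, 0)) / 3.0;
    double gy = (vertices(ia, 1) + vertices(ib, 1) + vertices(ic, 1)) / 3.0;
    double gz = (vertices(ia, 2) + vertices(ib, 2) + vertices(ic, 2)) / 3.0;
    cx[f] = gx; cy[f] = gy; cz[f] = gz;
    double r2 = 0.0;
    const int ids[3] = {ia, ib, ic};
    for (int t = 0; t < 3; ++t) {
      double dx = vertices(ids[t], 0) - gx;
      double dy = vertices(ids[t], 1) - gy;
      double dz = vertices(ids[t], 2) - gz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  double a[3], b[3], c[3], p[3], out[3], bary[3];
  for (int i = 0; i < Q; ++i) {
    p[0] = queries(i, 0); p[1] = queries(i, 1); p[2] = queries(i, 2);
    double best = DBL_MAX;  // squared distance
    double bestd = DBL_MAX; // distance (for pruning)
    for (int f = 0; f < F; ++f) {
      double dx = cx[f] - p[0], dy = cy[f] - p[1], dz = cz[f] - p[2];
      double dcen = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dcen - rad[f] >= bestd) continue;  // cannot beat current best
      const int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1,
                ic = faces(f, 2) - 1;
      for (int k = 0; k < 3; ++k) {
        a[k] = vertices(ia, k);
        b[k] = vertices(ib, k);
        c[k] = vertices(ic, k);
      }
      closest_on_triangle(p, a, b, c, out, bary);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = out[k] - p[k];
        d2 += d * d;
      }
      if (d2 < best) {
        best = d2;
        bestd = std::sqrt(d2);
        fidx[i] = f + 1;
        for (int k = 0; k < 3; ++k) {
          pts(i, k) = out[k];
          bmat(i, k) = bary[k];
        }
      }
    }
    dist[i] = std::sqrt(best);
  }
  return List::create(_["point"] = pts, _["face"] = fidx, _["dist"] = dist,
                      _["bary"] = bmat);
}
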