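#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Brute-force nearest neighbour: for each row of `query`, the index (1-based)
// of the closest row of `ref` and the distance. Ties broken by lowest index.
// O(N*M) but in C at the sizes ICP uses (~1e3 x 1e4) this is faster than
// building a tree per iteration in R.
// [[Rcpp::export]]
List nn_bruteforce_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int besti = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = ref(j, 0) - qx;
      const double dy = ref(j, 1) - qy;
      const double dz = ref(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = j; }
    }
    idx[i] = besti + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Exact nearest neighbour via a uniform grid over `ref`. Returns identical
// results to nn_bruteforce_cpp (including lowest-index tie-breaking): the
// shell search is run until no closer cell can exist. Query points may lie
// outside the grid (distance bound still valid after clamping).
// [[Rcpp::export]]
List nn_grid_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) { mn[k] = R_PosInf; mx[k] = R_NegInf; }
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < 3; ++k) {
      const double v = ref(j, k);
      if (v < mn[k]) mn[k] = v;
      if (v > mx[k]) mx[k] = v;
    }
  double ext[3];
  double vol = 1.0;
  for (int k = 0; k < 3; ++k) {
    ext[k] = mx[k] - mn[k];
    vol *= (ext[k] > 0 ? ext[k] : 1.0);
  }
  double cell = std::cbrt(vol / std::max(m, 1));
  if (!(cell > 0)) cell = 1.0;
  int dim[3];
  for (int k = 0; k < 3; ++k) {
    dim[k] = std::max(1, std::min(256, (int)(ext[k] / cell) + 1));
  }
  const int ncell = dim[0] * dim[1] * dim[2];
  std::vector<int> counts(ncell + 1, 0);
  std::vector<int> ci(m);
  for (int j = 0; j < m; ++j) {
    int idx3[3];
    for (int k = 0; k < 3; ++k) {
      int c = (int)((ref(j, k) - mn[k]) / cell);
      idx3[k] = std::max(0, std::min(dim[k] - 1, c));
    }
    ci[j] = (idx3[2] * dim[1] + idx3[1]) * dim[0] + idx3[0];
    counts[ci[j] + 1]++;
  }
  for (int c = 0; c < ncell; ++c) counts[c + 1] += counts[c];
  std::vector<int> bucket(m);
  {
    std::vector<int> cur(counts.begin(), counts.end() - 1);
    for (int j = 0; j < m; ++j) bucket[cur[ci[j]]++] = j;
  }
  IntegerVector out_idx(n);
  NumericVector out_dist(n);
  const int rmax = std::max(dim[0], std::max(dim[1], dim[2]));
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int iq[3];
    const double q3[3] = { qx, qy, qz };
    for (int k = 0; k < 3; ++k) {
      int c = (int)((q3[k] - mn[k]) / cell);
      iq[k] = std::max(0, std::min(dim[k] - 1, c));
    }
    double best = R_PosInf;
    int besti = -1;
    for (int r = 0; r <= rmax; ++r) {
      if (besti >= 0 && (double)(r - 1) * cell > std::sqrt(best)) break;
      const int x0 = std::max(0, iq[0] - r), x1 = std::min(dim[0] - 1, iq[0] + r);
      const int y0 = std::max(0, iq[1] - r), y1 = std::min(dim[1] - 1, iq[1] + r);
      const int z0 = std::max(0, iq[2] - r), z1 = std::min(dim[2] - 1, iq[2] + r);
      for (int z = z0; z <= z1; ++z) {
        const bool zedge = (z == iq[2] - r) || (z == iq[2] + r);
        for (int y = y0; y <= y1; ++y) {
          const bool yedge = (y == iq[1] - r) || (y == iq[1] + r);
          for (int x = x0; x <= x1; ++x) {
            const bool xedge = (x == iq[0] - r) || (x == iq[0] + r);
            if (r > 0 && !zedge && !yedge && !xedge) continue;  // interior: done earlier
            const int c = (z * dim[1] + y) * dim[0] + x;
            for (int b = counts[c]; b < counts[c + 1]; ++b) {
              const int j = bucket[b];
              const double dx = ref(j, 0) - qx;
              const double dy = ref(j, 1) - qy;
              const double dz = ref(j, 2) - qz;
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best || (d2 == best && j < besti)) { best = d2; besti = j; }
            }
          }
        }
      }
    }
    out_idx[i] = besti + 1;
    out_dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_dist);
}

// Moller-Trumbore ray/triangle intersection for a batch of rays against one
// triangle soup. Returns the smallest positive hit parameter t per ray
// (Inf when the ray misses everything). Hits with t <= eps are ignored so a
// ray leaving a surface point does not hit its own triangle.
// [[Rcpp::export]]
NumericVector ray_mesh_hits_cpp(NumericMatrix origins, NumericMatrix dirs,
                                NumericMatrix v0, NumericMatrix v1,
                                NumericMatrix v2, double eps) {
  const int nr = origins.nrow(), nt = v0.nrow();
  // flatten triangle data once: per-triangle base vertex and edges
  std::vector<double> bx(nt), by(nt), bz(nt);
  std::vector<double> e1x(nt), e1y(nt), e1z(nt);
  std::vector<double> e2x(nt), e2y(nt), e2z(nt);
  for (int j = 0; j < nt; ++j) {
    bx[j] = v0(j, 0); by[j] = v0(j, 1); bz[j] = v0(j, 2);
    e1x[j] = v1(j, 0) - bx[j]; e1y[j] = v1(j, 1) - by[j];
    e1z[j] = v1(j, 2) - bz[j];
    e2x[j] = v2(j, 0) - bx[j]; e2y[j] = v2(j, 1) - by[j];
    e2z[j] = v2(j, 2) - bz[j];
  }
  NumericVector tmin(nr, R_PosInf);
  for (int i = 0; i < nr; ++i) {
    const double ox = origins(i, 0), oy = origins(i, 1), oz = origins(i, 2);
    const double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nt; ++j) {
      // p = d x e2
      const double px = dy * e2z[j] - dz * e2y[j];
      const double py = dz * e2x[j] - dx * e2z[j];
      const double pz = dx * e2y[j] - dy * e2x[j];
      const double det = e1x[j] * px + e1y[j] * py + e1z[j] * pz;
      if (std::fabs(det) < 1e-12) continue;
      const double inv = 1.0 / det;
      const double tx = ox - bx[j];
      const double ty = oy - by[j];
      const double tz = oz - bz[j];
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      // q = t x e1
      const double qx = ty * e1z[j] - tz * e1y[j];
      const double qy = tz * e1x[j] - tx * e1z[j];
      const double qz = tx * e1y[j] - ty * e1x[j];
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      const double t = (e2x[j] * qx + e2y[j] * qy + e2z[j] * qz) * inv;
      if (t > eps && t < best) best = t;
    }
    tmin[i] = best;
  }
  return tmin;
}
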