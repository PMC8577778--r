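// Mesh voxelization by parity ray casting along +x.
// A voxel is occupied iff its center lies inside the closed surface.
// Rays hitting a triangle edge/vertex (degenerate parity) are re-cast
// with a small deterministic jitter.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tri {
  double x0, y0, z0, x1, y1, z1, x2, y2, z2;
  double ylo, yhi, zlo, zhi;
};

// Returns: 0 = miss, 1 = hit (xhit set), 2 = degenerate (edge/vertex graze)
int ray_hit(const Tri &t, double py, double pz, double tol, double &xhit) {
  const double e1y = t.y1 - t.y0, e1z = t.z1 - t.z0;
  const double e2y = t.y2 - t.y0, e2z = t.z2 - t.z0;
  const double det = e1y * e2z - e2y * e1z;
  if (std::fabs(det) < 1e-14) return 0;  // triangle parallel to ray
  const double dy = py - t.y0, dz = pz - t.z0;
  const double u = (dy * e2z - dz * e2y) / det;
  const double v = (e1y * dz - e1z * dy) / det;
  const double w = 1.0 - u - v;
  if (u < -tol || v < -tol || w < -tol) return 0;
  if (u < tol || v < tol || w < tol) return 2;
  xhit = w * t.x0 + u * t.x1 + v * t.x2;
  return 1;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix tri, double h, NumericVector origin,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ntri = tri.nrow() / 3;
  std::vector<Tri> T(ntri);
  for (int t = 0; t < ntri; ++t) {
    Tri &q = T[t];
    q.x0 = tri(3 * t, 0);     q.y0 = tri(3 * t, 1);     q.z0 = tri(3 * t, 2);
    q.x1 = tri(3 * t + 1, 0); q.y1 = tri(3 * t + 1, 1); q.z1 = tri(3 * t + 1, 2);
    q.x2 = tri(3 * t + 2, 0); q.y2 = tri(3 * t + 2, 1); q.z2 = tri(3 * t + 2, 2);
    q.ylo = std::min({q.y0, q.y1, q.y2}); q.yhi = std::max({q.y0, q.y1, q.y2});
    q.zlo = std::min({q.z0, q.z1, q.z2}); q.zhi = std::max({q.z0, q.z1, q.z2});
  }

  // bin triangles by the (j, k) rays their yz bounding box overlaps
  std::vector<std::vector<int>> bins((size_t)ny * nz);
  for (int t = 0; t < ntri; ++t) {
    int j0 = std::max(0, (int)std::floor((T[t].ylo - origin[1]) / h - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((T[t].yhi - origin[1]) / h));
    int k0 = std::max(0, (int)std::floor((T[t].zlo - origin[2]) / h - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((T[t].zhi - origin[2]) / h));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)j + (size_t)ny * k].push_back(t);
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> hits;
  const double tol = 1e-10;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const std::vector<int> &bin = bins[(size_t)j + (size_t)ny * k];
      if (bin.empty()) continue;
      double py = origin[1] + (j + 0.5) * h;
      double pz = origin[2] + (k + 0.5) * h;
      bool ok = false;
      for (int attempt = 0; attempt < 6 && !ok; ++attempt) {
        hits.clear();
        ok = true;
        for (int idx : bin) {
          double xh;
          int r = ray_hit(T[idx], py, pz, tol, xh);
          if (r == 2) { ok = false; break; }
          if (r == 1) hits.push_back(xh);
        }
        if (!ok) {  // deterministic jitter, grows with attempt
          double d = h * 3.7e-5 * (attempt + 1);
          py += d; pz += d * 1.618;
        }
      }
      if (!ok) continue;  // give up: treat ray as outside everywhere
      std::sort(hits.begin(), hits.end());
      for (int i = 0; i < nx; ++i) {
        double cx = origin[0] + (i + 0.5) * h;
        // parity of crossings beyond the center
        size_t above = hits.end() -
          std::upper_bound(hits.begin(), hits.end(), cx);
        if (above & 1)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}
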