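#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// Multi-source flood fill on a 3D lattice stored column-major as (nz, ny,
// nx). A voxel is reachable iff it is admissible and connected to a source
// through admissible voxels; sources themselves are enqueued only if
// admissible. Connectivity is 6, 18 or 26.
// [[Rcpp::export(rng = false)]]
LogicalVector cpp_flood(LogicalVector admissible, IntegerVector dims,
                        IntegerVector sources, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> vis(n, 0);
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < sources.size(); ++s) {
    R_xlen_t t = (R_xlen_t)sources[s] - 1;
    if (t >= 0 && t < n && !vis[t] && admissible[t]) {
      vis[t] = 1;
      q.push(t);
    }
  }
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dz, dy, dx});
      }
  while (!q.empty()) {
    R_xlen_t t = q.front();
    q.pop();
    int k = (int)(t % nz);
    R_xlen_t rest = t / nz;
    int j = (int)(rest % ny);
    int i = (int)(rest / ny);
    for (const auto &o : offs) {
      int kk = k + o[0], jj = j + o[1], ii = i + o[2];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
        continue;
      R_xlen_t tt = ((R_xlen_t)ii * ny + jj) * nz + kk;
      if (!vis[tt] && admissible[tt]) {
        vis[tt] = 1;
        q.push(tt);
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = vis[t] != 0;
  return out;
}

// For each row of `a` (points in mm), the Euclidean distance to the nearest
// row of `b`. Brute-force exact; used by the symmetric surface distances.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b) {
  const R_xlen_t na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (R_xlen_t i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (R_xlen_t j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
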