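#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---- median filter ---------------------------------------------------------

// Square-window median filter; edges use the truncated window.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter2d(const NumericMatrix& img, int radius) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      buf.clear();
      const int i0 = std::max(0, i - radius), i1 = std::min(ny - 1, i + radius);
      const int j0 = std::max(0, j - radius), j1 = std::min(nx - 1, j + radius);
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) buf.push_back(img(ii, jj));
      const size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        m = 0.5 * (m + buf[mid - 1]);
      }
      out(i, j) = m;
    }
  }
  return out;
}

// ---- rolling-ball background ----------------------------------------------

// Grayscale opening with a ball structuring element of the given radius
// (in pixels): erosion with the ball height profile followed by dilation.
// Returns the background estimate; subtract it from the image upstream.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball_background(const NumericMatrix& img, double radius) {
  const int ny = img.nrow(), nx = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> di, dj;
  std::vector<double> h;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      const double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        di.push_back(a); dj.push_back(b);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  const int K = (int)h.size();
  NumericMatrix ero(ny, nx), bg(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        const double v = img(ii, jj) - h[k];
        if (v < m) m = v;
      }
      ero(i, j) = m;
    }
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        const double v = ero(ii, jj) + h[k];
        if (v > m) m = v;
      }
      bg(i, j) = m;
    }
  return bg;
}

// ---- connected-component labelling ----------------------------------------

// BFS labelling of a binary 2D or 3D array. connectivity: 1 = faces only
// (4 / 6 neighbours), 2 = full (8 / 26 neighbours). dim is c(ny, nx[, nz]).
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask,
                                   const IntegerVector& dim,
                                   int connectivity) {
  const int nd = dim.size();
  const int ny = dim[0], nx = dim[1], nz = (nd == 3) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<int> off_i, off_j, off_k;
  for (int dk = (nd == 3 ? -1 : 0); dk <= (nd == 3 ? 1 : 0); ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int ord = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 1 && ord > 1) continue;
        off_i.push_back(di); off_j.push_back(dj); off_k.push_back(dk);
      }
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t p = q.front(); q.pop();
      const int k = (int)(p / ((R_xlen_t)ny * nx));
      const int j = (int)((p / ny) % nx);
      const int i = (int)(p % ny);
      for (size_t m = 0; m < off_i.size(); ++m) {
        const int ii = i + off_i[m], jj = j + off_j[m], kk = k + off_k[m];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz) continue;
        const R_xlen_t pp = (R_xlen_t)kk * ny * nx + (R_xlen_t)jj * ny + ii;
        if (mask[pp] && lab[pp] == 0) { lab[pp] = next; q.push(pp); }
      }
    }
  }
  lab.attr("max") = next;
  return lab;
}

// ---- 3D thinning -----------------------------------------------------------

namespace {

// Check whether the centre of a 3x3x3 neighbourhood is a simple point:
// (a) the foreground of the 26-neighbourhood forms one 26-connected
//     component, and
// (b) the background restricted to the 18-neighbourhood forms one
//     6-connected component that touches a face neighbour.
bool is_simple(const bool nb[27]) {
  // index = (dz+1)*9 + (dy+1)*3 + (dx+1); centre = 13
  static const int face[6] = {4, 10, 12, 14, 16, 22};
  // (a) foreground 26-connectivity over the 26 neighbours
  int fg[26], nfg = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) fg[nfg++] = i;
  if (nfg == 0) return false;
  {
    bool seen[27] = {false};
    std::queue<int> q;
    q.push(fg[0]); seen[fg[0]] = true;
    int cnt = 1;
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      const int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int m = 0; m < nfg; ++m) {
        const int s = fg[m];
        if (seen[s]) continue;
        const int sx = s % 3, sy = (s / 3) % 3, sz = s / 9;
        if (std::abs(px - sx) <= 1 && std::abs(py - sy) <= 1 &&
            std::abs(pz - sz) <= 1) {
          seen[s] = true; q.push(s); ++cnt;
        }
      }
    }
    if (cnt != nfg) return false;
  }
  // (b) background 6-connectivity within the 18-neighbourhood
  bool in18[27] = {false};
  for (int i = 0; i < 27; ++i) {
    if (i == 13) continue;
    const int dx = i % 3 - 1, dy = (i / 3) % 3 - 1, dz = i / 9 - 1;
    if (std::abs(dx) + std::abs(dy) + std::abs(dz) <= 2) in18[i] = true;
  }
  int start = -1;
  for (int f = 0; f < 6; ++f) if (!nb[face[f]]) { start = face[f]; break; }
  if (start < 0) return false;  // interior voxel
  bool seen[27] = {false};
  std::queue<int> q;
  q.push(start); seen[start] = true;
  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int px = p % 3, py = (p / 3) % 3, pz = p / 9;
    for (int s = 0; s < 27; ++s) {
      if (seen[s] || !in18[s] || nb[s]) continue;
      const int sx = s % 3, sy = (s / 3) % 3, sz = s / 9;
      if (std::abs(px - sx) + std::abs(py - sy) + std::abs(pz - sz) == 1) {
        seen[s] = true; q.push(s);
      }
    }
  }
  for (int f = 0; f < 6; ++f)
    if (!nb[face[f]] && !seen[face[f]]) return false;
  return true;
}

}  // namespace

// Topology-preserving 3D thinning by directional border peeling with
// endpoint preservation. Voxels are deleted only if simple; deletions are
// applied sequentially with re-checking so connectivity is never broken.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(const LogicalVector& vol, const IntegerVector& dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<char> v(n);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = vol[i] ? 1 : 0;
  auto at = [&](int i, int j, int k) -> char {
    if (i < 0 || i >= ny || j < 0 || j >= nx || k < 0 || k >= nz) return 0;
    return v[(R_xlen_t)k * ny * nx + (R_xlen_t)j * ny + i];
  };
  auto nbhd = [&](int i, int j, int k, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[(dz + 1) * 9 + (dx + 1) * 3 + (dy + 1)] =
              at(i + dy, j + dx, k + dz) != 0;
    // nb is indexed so that axis order matches is_simple's (x fastest);
    // the mapping only needs to be a consistent relabelling of the cube.
  };
  auto n26 = [&](int i, int j, int k) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (at(i + dy, j + dx, k + dz)) ++c;
        }
    return c;
  };
  const int dir_i[6] = {1, -1, 0, 0, 0, 0};
  const int dir_j[6] = {0, 0, 1, -1, 0, 0};
  const int dir_k[6] = {0, 0, 0, 0, 1, -1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<R_xlen_t> cand;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < nx; ++j)
          for (int i = 0; i < ny; ++i) {
            if (!at(i, j, k)) continue;
            if (at(i + dir_i[d], j + dir_j[d], k + dir_k[d])) continue;
            if (n26(i, j, k) <= 1) continue;  // endpoint
            cand.push_back((R_xlen_t)k * ny * nx + (R_xlen_t)j * ny + i);
          }
      for (R_xlen_t p : cand) {
        const int k = (int)(p / ((R_xlen_t)ny * nx));
        const int j = (int)((p / ny) % nx);
        const int i = (int)(p % ny);
        if (n26(i, j, k) <= 1) continue;
        bool nb[27];
        nbhd(i, j, k, nb);
        if (is_simple(nb)) { v[p] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dim;
  return out;
}
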