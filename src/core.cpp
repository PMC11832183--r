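// Low-level 3D grid operations shared by the segmentation, skeletonization
// and morphology layers. Arrays arrive as R column-major vectors with
// dims = (n1, n2, n3); the first index varies fastest.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static inline size_t lin(int i, int j, int k, int n1, int n2) {
  return (size_t)i + (size_t)n1 * ((size_t)j + (size_t)n2 * (size_t)k);
}

// ---------------------------------------------------------------------------
// Separable convolution with replicate (clamped) borders.

static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int n1, int n2, int n3, int axis,
                      const std::vector<double>& w) {
  const int r = ((int)w.size() - 1) / 2;
  const int na = axis == 0 ? n1 : (axis == 1 ? n2 : n3);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int c = axis == 0 ? i : (axis == 1 ? j : k);
        double s = 0.0;
        for (int t = -r; t <= r; ++t) {
          int cc = c + t;
          if (cc < 0) cc = 0;
          if (cc >= na) cc = na - 1;
          const int ii = axis == 0 ? cc : i;
          const int jj = axis == 1 ? cc : j;
          const int kk = axis == 2 ? cc : k;
          s += w[t + r] * in[lin(ii, jj, kk, n1, n2)];
        }
        out[lin(i, j, k, n1, n2)] = s;
      }
}

static std::vector<double> gauss_kernel(double sigma_vox) {
  int r = (int)std::ceil(3.0 * sigma_vox);
  if (r < 1) r = 1;
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    w[t + r] = std::exp(-0.5 * (double)t * t / (sigma_vox * sigma_vox));
    s += w[t + r];
  }
  for (double& v : w) v /= s;
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          NumericVector sigma_vox) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma_vox[axis] <= 0) continue;  // axis disabled (2D per-slice mode)
    std::vector<double> w = gauss_kernel(sigma_vox[axis]);
    conv_axis(a, b, n1, n2, n3, axis, w);
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// op: 0 = mean, 1 = min, 2 = max; separable box of half-width radius[axis].
static void box_axis(const std::vector<double>& in, std::vector<double>& out,
                     int n1, int n2, int n3, int axis, int r, int op) {
  const int na = axis == 0 ? n1 : (axis == 1 ? n2 : n3);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int c = axis == 0 ? i : (axis == 1 ? j : k);
        double acc = op == 0 ? 0.0
                             : (op == 1 ? std::numeric_limits<double>::infinity()
                                        : -std::numeric_limits<double>::infinity());
        int cnt = 0;
        for (int t = -r; t <= r; ++t) {
          int cc = c + t;
          if (cc < 0 || cc >= na) continue;  // shrink window at borders
          const int ii = axis == 0 ? cc : i;
          const int jj = axis == 1 ? cc : j;
          const int kk = axis == 2 ? cc : k;
          const double v = in[lin(ii, jj, kk, n1, n2)];
          if (op == 0) { acc += v; ++cnt; }
          else if (op == 1) { if (v < acc) acc = v; }
          else { if (v > acc) acc = v; }
        }
        out[lin(i, j, k, n1, n2)] = op == 0 ? acc / cnt : acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_box3d(NumericVector vol, IntegerVector dims,
                        IntegerVector radius_vox, int op) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    if (radius_vox[axis] <= 0) continue;
    box_axis(a, b, n1, n2, n3, axis, radius_vox[axis], op);
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// Connected-component labeling, connectivity 6 / 18 / 26.

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = (size_t)n1 * n2 * n3;
  std::vector<int> off1, off2, off3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        const int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off1.push_back(a); off2.push_back(b); off3.push_back(c);
      }
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % n1);
      const int j = (int)((cur / n1) % n2);
      const int k = (int)(cur / ((size_t)n1 * n2));
      for (size_t t = 0; t < off1.size(); ++t) {
        const int ii = i + off1[t], jj = j + off2[t], kk = k + off3[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        const size_t q = lin(ii, jj, kk, n1, n2);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 3D homotopic thinning to a one-voxel-wide curve skeleton.
//
// Foreground uses 26-connectivity, background 6-connectivity. A voxel is
// "simple" (deletable without changing topology) when (a) the foreground of
// its 26-neighborhood forms exactly one 26-connected component and (b) the
// background restricted to its 18-neighborhood forms exactly one 6-connected
// component containing a face neighbor. Simple non-endpoint border voxels
// are deleted sequentially (re-checked at deletion time, which preserves
// homotopy) in six directional subiterations until stable.

namespace thin_tables {
  bool built = false;
  bool adj26[27][27];
  bool adj6[27][27];
  bool in18[27];
  bool face[27];
  int offs[27][3];

  void build() {
    if (built) return;
    int l = 0;
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          // local index: a fastest to mirror global layout (irrelevant, but fixed)
          l = (a + 1) + 3 * ((b + 1) + 3 * (c + 1));
          offs[l][0] = a; offs[l][1] = b; offs[l][2] = c;
          const int m = std::abs(a) + std::abs(b) + std::abs(c);
          in18[l] = (m == 1 || m == 2);
          face[l] = (m == 1);
        }
    for (int p = 0; p < 27; ++p)
      for (int q = 0; q < 27; ++q) {
        const int da = std::abs(offs[p][0] - offs[q][0]);
        const int db = std::abs(offs[p][1] - offs[q][1]);
        const int dc = std::abs(offs[p][2] - offs[q][2]);
        const int cheb = std::max(da, std::max(db, dc));
        adj26[p][q] = (p != q) && cheb == 1;
        adj6[p][q] = (p != q) && (da + db + dc) == 1;
      }
    built = true;
  }
}

static inline int fg_neighbor_count(const bool nb[27]) {
  int c = 0;
  for (int l = 0; l < 27; ++l)
    if (l != 13 && nb[l]) ++c;
  return c;
}

static bool is_simple(const bool nb[27]) {
  using namespace thin_tables;
  // (a) one 26-component of foreground among the 26 neighbors
  int seen[27]; bool vis[27] = {false};
  int ncomp = 0;
  for (int l = 0; l < 27; ++l) {
    if (l == 13 || !nb[l] || vis[l]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int top = 0;
    seen[top++] = l; vis[l] = true;
    while (top > 0) {
      const int p = seen[--top];
      for (int q = 0; q < 27; ++q)
        if (q != 13 && nb[q] && !vis[q] && adj26[p][q]) {
          vis[q] = true; seen[top++] = q;
        }
    }
  }
  if (ncomp != 1) return false;
  // (b) one 6-component of background within N18 touching a face neighbor
  bool bvis[27] = {false};
  int nback = 0;
  for (int l = 0; l < 27; ++l) {
    if (!in18[l] || nb[l] || bvis[l]) continue;
    int top = 0;
    seen[top++] = l; bvis[l] = true;
    bool touches = face[l];
    while (top > 0) {
      const int p = seen[--top];
      for (int q = 0; q < 27; ++q)
        if (in18[q] && !nb[q] && !bvis[q] && adj6[p][q]) {
          bvis[q] = true;
          if (face[q]) touches = true;
          seen[top++] = q;
        }
    }
    if (touches) ++nback;
    if (nback > 1) return false;
  }
  return nback == 1;
}

static inline void gather(const std::vector<uint8_t>& m, int i, int j, int k,
                          int n1, int n2, int n3, bool nb[27]) {
  int l = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a, ++l) {
        const int ii = i + a, jj = j + b, kk = k + c;
        nb[l] = (ii >= 0 && ii < n1 && jj >= 0 && jj < n2 &&
                 kk >= 0 && kk < n3) &&
                m[lin(ii, jj, kk, n1, n2)] != 0;
      }
}

// Distance-ordered homotopic thinning: border voxels are deleted in order
// of increasing `priority` (the anisotropic distance-transform value), each
// deletion re-validated against the current state, so the result is a
// centered curve skeleton with topology identical to the input.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims,
                         NumericVector priority) {
  thin_tables::build();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = (size_t)n1 * n2 * n3;
  std::vector<uint8_t> m(n);
  for (size_t s = 0; s < n; ++s) m[s] = mask[s] ? 1 : 0;
  const bool use_prio = priority.size() == (R_xlen_t)n;
  const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::vector<size_t> cand;
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t s = 0; s < n; ++s) {
        if (!m[s]) continue;
        const int i = (int)(s % n1);
        const int j = (int)((s / n1) % n2);
        const int k = (int)(s / ((size_t)n1 * n2));
        const int ii = i + dir[d][0], jj = j + dir[d][1], kk = k + dir[d][2];
        const bool border =
            (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) ||
            m[lin(ii, jj, kk, n1, n2)] == 0;
        if (!border) continue;
        gather(m, i, j, k, n1, n2, n3, nb);
        if (fg_neighbor_count(nb) <= 1) continue;  // endpoint: keep
        if (is_simple(nb)) cand.push_back(s);
      }
      if (use_prio)
        std::stable_sort(cand.begin(), cand.end(),
                         [&](size_t a, size_t b) {
                           return priority[a] < priority[b];
                         });
      for (size_t t = 0; t < cand.size(); ++t) {
        const size_t s = cand[t];
        const int i = (int)(s % n1);
        const int j = (int)((s / n1) % n2);
        const int k = (int)(s / ((size_t)n1 * n2));
        gather(m, i, j, k, n1, n2, n3, nb);
        if (fg_neighbor_count(nb) <= 1) continue;
        if (!is_simple(nb)) continue;  // re-check: neighbors may be gone
        m[s] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = m[s] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Exact anisotropic Euclidean distance transform (distance from every voxel
// to the nearest seed voxel), separable lower-envelope algorithm on squared
// distances with per-axis sample spacing.

// "Unreachable" squared distance stands in for infinity; large enough to
// dominate any realistic grid extent, small enough to avoid overflow.
static const double DT_BIG = 1e30;

static void dt_line(std::vector<double>& f, double w, int n,
                    std::vector<int>& v, std::vector<double>& z,
                    std::vector<double>& d) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; }  // z[0] = -inf, so k never drops below 0
      else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector seeds, IntegerVector dims,
                        NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> D(n);
  for (size_t s = 0; s < n; ++s) D[s] = seeds[s] ? 0.0 : DT_BIG;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 0
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) f[i] = D[lin(i, j, k, n1, n2)];
      dt_line(f, spacing[0], n1, v, z, d);
      for (int i = 0; i < n1; ++i) D[lin(i, j, k, n1, n2)] = d[i];
    }
  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j) f[j] = D[lin(i, j, k, n1, n2)];
      dt_line(f, spacing[1], n2, v, z, d);
      for (int j = 0; j < n2; ++j) D[lin(i, j, k, n1, n2)] = d[j];
    }
  // axis 2
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k) f[k] = D[lin(i, j, k, n1, n2)];
      dt_line(f, spacing[2], n3, v, z, d);
      for (int k = 0; k < n3; ++k) D[lin(i, j, k, n1, n2)] = d[k];
    }
  NumericVector out(n);
  for (size_t s = 0; s < n; ++s)
    out[s] = (D[s] >= DT_BIG / 2) ? R_PosInf : std::sqrt(D[s]);
  return out;
}
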