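// n-D image kernels shared by the reference backend.
// Arrays arrive as flat vectors in R's column-major layout (first axis
// fastest); `dims` carries the axis sizes and `offsets` an L x ndim matrix of
// integer coordinate deltas describing a structuring element / footprint.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Grid {
  std::vector<int> dim;
  std::vector<int64_t> stride;
  int nd;
  int64_t n;
  explicit Grid(const IntegerVector& dims) {
    nd = dims.size();
    dim.assign(dims.begin(), dims.end());
    stride.resize(nd);
    int64_t s = 1;
    for (int a = 0; a < nd; ++a) { stride[a] = s; s *= dim[a]; }
    n = s;
  }
  void coords(int64_t idx, int* c) const {
    for (int a = 0; a < nd; ++a) { c[a] = (int)(idx % dim[a]); idx /= dim[a]; }
  }
};

// neighbour linear index or -1 when the offset leaves the grid
inline int64_t shift_idx(const Grid& g, const int* c, const int* off) {
  int64_t idx = 0;
  for (int a = 0; a < g.nd; ++a) {
    int ca = c[a] + off[a];
    if (ca < 0 || ca >= g.dim[a]) return -1;
    idx += (int64_t)ca * g.stride[a];
  }
  return idx;
}

std::vector<std::vector<int>> offset_rows(const IntegerMatrix& offsets) {
  std::vector<std::vector<int>> out(offsets.nrow());
  for (int i = 0; i < offsets.nrow(); ++i) {
    out[i].resize(offsets.ncol());
    for (int j = 0; j < offsets.ncol(); ++j) out[i][j] = offsets(i, j);
  }
  return out;
}

// linear deltas for the interior fast path + per-axis extents
struct FastOffsets {
  std::vector<int64_t> lin;
  std::vector<int> lo, hi; // per-axis min/max offset
  explicit FastOffsets(const Grid& g,
                       const std::vector<std::vector<int>>& off) {
    lin.resize(off.size());
    lo.assign(g.nd, 0); hi.assign(g.nd, 0);
    for (size_t k = 0; k < off.size(); ++k) {
      int64_t d = 0;
      for (int a = 0; a < g.nd; ++a) {
        d += (int64_t)off[k][a] * g.stride[a];
        lo[a] = std::min(lo[a], off[k][a]);
        hi[a] = std::max(hi[a], off[k][a]);
      }
      lin[k] = d;
    }
  }
  bool interior(const Grid& g, const int* c) const {
    for (int a = 0; a < g.nd; ++a)
      if (c[a] + lo[a] < 0 || c[a] + hi[a] >= g.dim[a]) return false;
    return true;
  }
};

} // namespace

// Connected-component labelling of a logical mask with arbitrary neighbour
// offsets (pass face offsets for standard connectivity, a ball for
// footprint-merged marker labelling).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets) {
  Grid g(dims);
  std::vector<std::vector<int>> off = offset_rows(offsets);
  IntegerVector lab(g.n, 0);
  std::vector<int64_t> stack;
  std::vector<int> c(g.nd);
  int next = 0;
  for (int64_t i = 0; i < g.n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      g.coords(cur, c.data());
      for (size_t k = 0; k < off.size(); ++k) {
        int64_t nb = shift_idx(g, c.data(), off[k].data());
        if (nb >= 0 && mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}

namespace {
// 1-D squared distance transform of a sampled function (Felzenszwalb-Huttenlocher)
void dt1d(const double* f, int n, double step2, double* d,
          std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300; z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= 1e290) { continue; }
    double s;
    while (true) {
      int p = v[k];
      if (f[p] >= 1e290) { // previous parabola at +inf: replace it
        if (k == 0) { v[0] = q; z[0] = -1e300; z[1] = 1e300; s = -1e300; break; }
        --k;
        continue;
      }
      s = ((f[q] + (double)q * q * step2) - (f[p] + (double)p * p * step2)) /
          (2.0 * step2 * (q - p));
      if (s <= z[k]) { --k; continue; }
      break;
    }
    if (v[k] != q) {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = 1e300;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    int p = v[k];
    double dq = (double)(q - p);
    d[q] = dq * dq * step2 + f[p];
  }
}
} // namespace

// Squared Euclidean distance (optionally anisotropic via `spacing`) from each
// TRUE voxel to the nearest FALSE voxel; FALSE voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  Grid g(dims);
  NumericVector out(g.n);
  for (int64_t i = 0; i < g.n; ++i) out[i] = mask[i] ? 1e300 : 0.0;
  std::vector<double> line, dline;
  std::vector<int> v;
  std::vector<double> z;
  for (int a = 0; a < g.nd; ++a) {
    int n = g.dim[a];
    if (n == 1) continue;
    double step2 = spacing[a] * spacing[a];
    line.resize(n); dline.resize(n);
    v.resize(n); z.resize(n + 1);
    int64_t stride = g.stride[a];
    int64_t nlines = g.n / n;
    std::vector<int> c(g.nd);
    for (int64_t l = 0; l < nlines; ++l) {
      // base index of this line: decompose l over the remaining axes
      int64_t rem = l, base = 0;
      for (int b = 0; b < g.nd; ++b) {
        if (b == a) continue;
        int cb = (int)(rem % g.dim[b]);
        rem /= g.dim[b];
        base += (int64_t)cb * g.stride[b];
      }
      bool all_inf = true;
      for (int q = 0; q < n; ++q) {
        line[q] = out[base + (int64_t)q * stride];
        if (line[q] < 1e290) all_inf = false;
      }
      if (all_inf) continue;
      dt1d(line.data(), n, step2, dline.data(), v, z);
      for (int q = 0; q < n; ++q) out[base + (int64_t)q * stride] = dline[q];
    }
  }
  return out;
}

// Seeded watershed: flood `relief` (low values first) from non-zero markers,
// restricted to `mask`, face connectivity; FIFO order breaks ties so the
// result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  IntegerVector lab(g.n, 0);
  struct Node { double val; int64_t order; int64_t idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.val != b.val) return a.val > b.val;
      return a.order > b.order;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  int64_t counter = 0;
  for (int64_t i = 0; i < g.n; ++i) {
    if (markers[i] != 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push({relief[i], counter++, i});
    }
  }
  std::vector<int> c(g.nd), off(g.nd, 0);
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    g.coords(nd.idx, c.data());
    int cur = lab[nd.idx];
    for (int a = 0; a < g.nd; ++a) {
      for (int s = -1; s <= 1; s += 2) {
        off[a] = s;
        int64_t nb = shift_idx(g, c.data(), off.data());
        off[a] = 0;
        if (nb >= 0 && mask[nb] && lab[nb] == 0) {
          lab[nb] = cur;
          pq.push({relief[nb], counter++, nb});
        }
      }
    }
  }
  return lab;
}

// Median filter over a footprint, nearest (clamped) border handling.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector img, IntegerVector dims,
                                IntegerMatrix offsets) {
  Grid g(dims);
  std::vector<std::vector<int>> off = offset_rows(offsets);
  FastOffsets fo(g, off);
  size_t L = off.size();
  NumericVector out(g.n);
  std::vector<double> buf(L);
  std::vector<int> c(g.nd), cc(g.nd);
  for (int64_t i = 0; i < g.n; ++i) {
    g.coords(i, c.data());
    if (fo.interior(g, c.data())) {
      for (size_t k = 0; k < L; ++k) buf[k] = img[i + fo.lin[k]];
    } else {
      for (size_t k = 0; k < L; ++k) {
        int64_t idx = 0;
        for (int a = 0; a < g.nd; ++a) {
          int ca = c[a] + off[k][a];
          if (ca < 0) ca = 0;
          if (ca >= g.dim[a]) ca = g.dim[a] - 1;
          idx += (int64_t)ca * g.stride[a];
        }
        buf[k] = img[idx];
      }
    }
    size_t mid = L / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (L % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      m = 0.5 * (m + lo);
    }
    out[i] = m;
  }
  return out;
}

// Local maxima over a footprint: voxel is a maximum when >= every in-bounds
// neighbour (plateaus are kept; merge them by labelling with the same
// footprint). Only voxels with candidate == TRUE are evaluated.
// [[Rcpp::export]]
LogicalVector cpp_local_max(NumericVector img, IntegerVector dims,
                            IntegerMatrix offsets, LogicalVector candidate) {
  Grid g(dims);
  std::vector<std::vector<int>> off = offset_rows(offsets);
  FastOffsets fo(g, off);
  LogicalVector out(g.n);
  std::vector<int> c(g.nd);
  for (int64_t i = 0; i < g.n; ++i) {
    if (!candidate[i]) { out[i] = false; continue; }
    g.coords(i, c.data());
    bool ok = true;
    if (fo.interior(g, c.data())) {
      for (size_t k = 0; k < off.size(); ++k)
        if (img[i + fo.lin[k]] > img[i]) { ok = false; break; }
    } else {
      for (size_t k = 0; k < off.size(); ++k) {
        int64_t nb = shift_idx(g, c.data(), off[k].data());
        if (nb >= 0 && img[nb] > img[i]) { ok = false; break; }
      }
    }
    out[i] = ok;
  }
  return out;
}

// Binary erosion/dilation with a footprint. Out-of-bounds samples take the
// operation's identity (erosion: TRUE, dilation: FALSE) so border regions are
// not clipped artificially.
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix offsets, bool dilate) {
  Grid g(dims);
  std::vector<std::vector<int>> off = offset_rows(offsets);
  FastOffsets fo(g, off);
  LogicalVector out(g.n);
  std::vector<int> c(g.nd);
  for (int64_t i = 0; i < g.n; ++i) {
    g.coords(i, c.data());
    bool acc = dilate ? false : true;
    if (fo.interior(g, c.data())) {
      for (size_t k = 0; k < off.size(); ++k) {
        bool v = mask[i + fo.lin[k]];
        if (dilate) { if (v) { acc = true; break; } }
        else        { if (!v) { acc = false; break; } }
      }
    } else {
      for (size_t k = 0; k < off.size(); ++k) {
        int64_t nb = shift_idx(g, c.data(), off[k].data());
        if (nb < 0) continue;
        if (dilate) { if (mask[nb]) { acc = true; break; } }
        else        { if (!mask[nb]) { acc = false; break; } }
      }
    }
    out[i] = acc;
  }
  return out;
}
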