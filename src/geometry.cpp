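// 3D geometry primitives with anisotropic voxel spacing.
// Index convention matches R arrays: dim = (n1, n2, n3), column-major,
// linear index = i + n1 * (j + n2 * k), all 0-based here.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing h; f holds squared distances, overwritten in place via buffers.
static void dt1d(std::vector<double>& f, double h, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double h2 = h * h;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { // both parabolas at infinity
      continue;
    }
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      if (fv == INF) { // previous vertex useless; replace
        --k;
        if (k < 0) break;
        continue;
      }
      s = ((fq + (double)q * q * h2) - (fv + (double)v[k] * v[k] * h2)) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double diff = (double)(q - v[k]);
    d[q] = (f[v[k]] == INF) ? INF : diff * diff * h2 + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance transform of a 3D mask: for every TRUE voxel, the
// distance (in spacing units) to the nearest FALSE voxel centre. FALSE
// voxels get 0. Entirely TRUE volumes get distance to the nearest face
// treated as outside (a virtual background layer is NOT added; such inputs
// return Inf and the caller decides).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(nn);
  for (R_xlen_t i = 0; i < nn; ++i) out[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest varying)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      f.assign(n1, 0.0);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, spacing[0], d, v, z);
      for (int i = 0; i < n1; ++i) out[base + i] = f[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      f.assign(n2, 0.0);
      for (int j = 0; j < n2; ++j)
        f[j] = out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(f, spacing[1], d, v, z);
      for (int j = 0; j < n2; ++j)
        out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = f[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      f.assign(n3, 0.0);
      for (int k = 0; k < n3; ++k)
        f[k] = out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(f, spacing[2], d, v, z);
      for (int k = 0; k < n3; ++k)
        out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = f[k];
    }
  for (R_xlen_t i = 0; i < nn; ++i)
    if (out[i] != INF) out[i] = std::sqrt(out[i]);
  return out;
}

// 26-neighbourhood local maxima of `values` restricted to mask (values > 0).
// Plateau voxels all qualify; the caller collapses plateaus.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector values, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(nn, FALSE);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        double v = values[idx];
        if (!(v > 0)) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1 && ismax; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 ||
                  kk >= n3)
                continue;
              if (values[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)] > v)
                ismax = false;
            }
        out[idx] = ismax;
      }
  return out;
}

// Marker-based watershed by priority flood: flood the masked region from
// labelled markers in order of decreasing `priority` (e.g. a distance
// transform), 6-connectivity. Ties broken by insertion order (FIFO) for
// determinism. Returns a label volume; masked voxels unreachable from any
// marker stay 0.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority_, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(nn, 0);

  typedef std::tuple<double, long long, R_xlen_t> Node; // (-prio, order, idx)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long counter = 0;
  for (R_xlen_t i = 0; i < nn; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Node(-priority_[i], counter++, i));
    }
  }
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    R_xlen_t idx = std::get<2>(pq.top());
    pq.pop();
    int i = (int)(idx % n1);
    int j = (int)((idx / n1) % n2);
    int k = (int)(idx / ((R_xlen_t)n1 * n2));
    int l = lab[idx];
    for (int m = 0; m < 6; ++m) {
      int ii = i + d1[m], jj = j + d2[m], kk = k + d3[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      R_xlen_t nidx = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
      if (mask[nidx] && lab[nidx] == 0) {
        lab[nidx] = l;
        pq.push(Node(-priority_[nidx], counter++, nidx));
      }
    }
  }
  return lab;
}

// Grow existing labels into unlabelled masked voxels by multi-source BFS
// (6-connectivity): each unlabelled voxel takes the label of the nearest
// (in BFS hops) labelled voxel. Deterministic.
// [[Rcpp::export]]
IntegerVector cpp_grow_nearest(IntegerVector labels, LogicalVector mask,
                               IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab = clone(labels);
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < nn; ++i)
    if (lab[i] > 0 && mask[i]) q.push(i);
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    R_xlen_t idx = q.front();
    q.pop();
    int i = (int)(idx % n1);
    int j = (int)((idx / n1) % n2);
    int k = (int)(idx / ((R_xlen_t)n1 * n2));
    int l = lab[idx];
    for (int m = 0; m < 6; ++m) {
      int ii = i + d1[m], jj = j + d2[m], kk = k + d3[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      R_xlen_t nidx = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
      if (mask[nidx] && lab[nidx] == 0) {
        lab[nidx] = l;
        q.push(nidx);
      }
    }
  }
  return lab;
}

// Connected-component labelling of a 3D mask (BFS), connectivity 6 or 26.
// Labels are assigned in scan order of each component's first voxel, so the
// result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(nn, 0);
  std::vector<R_xlen_t> offs;
  std::vector<int> o1, o2, o3;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        o1.push_back(di);
        o2.push_back(dj);
        o3.push_back(dk);
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nn; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int i = (int)(idx % n1);
      int j = (int)((idx / n1) % n2);
      int k = (int)(idx / ((R_xlen_t)n1 * n2));
      for (size_t m = 0; m < o1.size(); ++m) {
        int ii = i + o1[m], jj = j + o2[m], kk = k + o3[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        R_xlen_t nidx = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[nidx] && lab[nidx] == 0) {
          lab[nidx] = next;
          stack.push_back(nidx);
        }
      }
    }
  }
  return lab;
}
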