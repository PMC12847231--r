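#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>

// k-nearest-neighbor distances via a kd-tree. Used by the
// Kozachenko-Leonenko entropy estimator, where each point needs the
// Euclidean distance to its k-th nearest neighbor among the other points.
// Dimensions are small (1-4) and point counts up to ~1e6.

namespace {

struct KdTree {
  const double *pts; // column-major m x d
  int m, d;
  std::vector<int> idx;      // permutation of point indices
  std::vector<int> left_, right_, split_dim;
  std::vector<double> split_val;
  std::vector<int> beg_, end_; // leaf ranges into idx
  static const int LEAF = 16;

  double coord(int i, int j) const { return pts[i + (size_t)j * m]; }

  int build(int lo, int hi, int depth) {
    int node = (int)left_.size();
    left_.push_back(-1); right_.push_back(-1);
    split_dim.push_back(-1); split_val.push_back(0.0);
    beg_.push_back(lo); end_.push_back(hi);
    if (hi - lo <= LEAF) return node;
    // split on dimension with largest spread
    int dim = 0; double best_spread = -1.0;
    for (int j = 0; j < d; ++j) {
      double mn = coord(idx[lo], j), mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = coord(idx[i], j);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > best_spread) { best_spread = mx - mn; dim = j; }
    }
    if (best_spread <= 0.0) return node; // all points identical: leaf
    int mid = (lo + hi) / 2;
    const double *p = pts; int mm = m;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [p, mm, dim](int a, int b) {
                       return p[a + (size_t)dim * mm] < p[b + (size_t)dim * mm];
                     });
    split_dim[node] = dim;
    split_val[node] = coord(idx[mid], dim);
    int l = build(lo, mid, depth + 1);
    left_[node] = l;
    int r = build(mid, hi, depth + 1);
    right_[node] = r;
    return node;
  }

  void init(const double *p, int m_, int d_) {
    pts = p; m = m_; d = d_;
    idx.resize(m);
    for (int i = 0; i < m; ++i) idx[i] = i;
    left_.reserve(2 * m / LEAF + 4);
    build(0, m, 0);
  }

  // max-heap of squared distances, size k, excluding the query point itself
  void query(int self, int node, const std::vector<double> &q, int k,
             std::priority_queue<double> &heap) const {
    if (split_dim[node] < 0) { // leaf
      for (int i = beg_[node]; i < end_[node]; ++i) {
        int j = idx[i];
        if (j == self) continue;
        double s = 0.0;
        for (int t = 0; t < d; ++t) {
          double diff = coord(j, t) - q[t];
          s += diff * diff;
        }
        if ((int)heap.size() < k) heap.push(s);
        else if (s < heap.top()) { heap.pop(); heap.push(s); }
      }
      return;
    }
    double delta = q[split_dim[node]] - split_val[node];
    int near = delta <= 0 ? left_[node] : right_[node];
    int far = delta <= 0 ? right_[node] : left_[node];
    query(self, near, q, k, heap);
    if ((int)heap.size() < k || delta * delta < heap.top())
      query(self, far, q, k, heap);
  }
};

} // namespace

// [[Rcpp::export(name = ".knn_distances")]]
Rcpp::NumericMatrix knn_distances_cpp(Rcpp::NumericMatrix x, int k) {
  int m = x.nrow(), d = x.ncol();
  if (k < 1 || k >= m) Rcpp::stop("need 1 <= k < nrow(x)");
  KdTree tree;
  tree.init(x.begin(), m, d);
  Rcpp::NumericMatrix out(m, k); // distances to 1st..kth neighbor
  std::vector<double> q(d);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < d; ++j) q[j] = x(i, j);
    std::priority_queue<double> heap;
    tree.query(i, 0, q, k, heap);
    for (int j = k - 1; j >= 0; --j) {
      out(i, j) = std::sqrt(heap.top());
      heap.pop();
    }
  }
  return out;
}
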