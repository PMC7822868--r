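#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Small kd-tree for k-nearest-neighbour distances among the sample points
// themselves (each query point is excluded from its own neighbour list).
// Euclidean metric; dimensions are taken as supplied, so any standardisation
// happens on the R side. Splits are on the dimension of largest spread at
// the median; leaves are scanned linearly.
namespace {

struct KDTree {
  const double *x;  // column-major n x d
  int n, d;
  std::vector<int> idx;
  struct Node {
    int lo, hi;      // range in idx
    int dim;         // split dimension, -1 for leaf
    double split;
    int left, right;
  };
  std::vector<Node> nodes;
  static const int LEAF = 24;

  KDTree(const double *x_, int n_, int d_) : x(x_), n(n_), d(d_), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / LEAF + 8);
    build(0, n);
  }

  inline double coord(int i, int dim) const {
    return x[i + static_cast<size_t>(dim) * n];
  }

  int build(int lo, int hi) {
    int id = static_cast<int>(nodes.size());
    nodes.push_back({lo, hi, -1, 0.0, -1, -1});
    if (hi - lo <= LEAF) return id;
    int best_dim = 0;
    double best_spread = -1.0;
    for (int dim = 0; dim < d; ++dim) {
      double mn = std::numeric_limits<double>::infinity(), mx = -mn;
      for (int i = lo; i < hi; ++i) {
        double v = coord(idx[i], dim);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      double spread = mx - mn;
      if (spread > best_spread) { best_spread = spread; best_dim = dim; }
    }
    if (best_spread <= 0.0) return id;  // all points identical: keep as leaf
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, best_dim) < coord(b, best_dim); });
    double split = coord(idx[mid], best_dim);
    int left = build(lo, mid);
    int right = build(mid, hi);
    nodes[id].dim = best_dim;
    nodes[id].split = split;
    nodes[id].left = left;
    nodes[id].right = right;
    return id;
  }

  // max-heap of squared distances of current k best
  void search(int node, const double *q, int self, int k,
              std::priority_queue<double> &heap) const {
    const Node &nd = nodes[node];
    if (nd.dim < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx[i];
        if (j == self) continue;
        double s = 0.0;
        for (int dim = 0; dim < d; ++dim) {
          double diff = coord(j, dim) - q[dim];
          s += diff * diff;
        }
        if (static_cast<int>(heap.size()) < k) heap.push(s);
        else if (s < heap.top()) { heap.pop(); heap.push(s); }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int first = diff < 0 ? nd.left : nd.right;
    int second = diff < 0 ? nd.right : nd.left;
    search(first, q, self, k, heap);
    if (static_cast<int>(heap.size()) < k || diff * diff < heap.top())
      search(second, q, self, k, heap);
  }
};

}  // namespace

//' @useDynLib surfid, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export(name = ".kth_nn_distance")]]
NumericVector kth_nn_distance(NumericMatrix x, int k) {
  int n = x.nrow(), d = x.ncol();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need more than k points");
  KDTree tree(REAL(x), n, d);
  NumericVector out(n);
  std::vector<double> q(d);
  for (int i = 0; i < n; ++i) {
    for (int dim = 0; dim < d; ++dim) q[dim] = x(i, dim);
    std::priority_queue<double> heap;
    tree.search(0, q.data(), i, k, heap);
    out[i] = std::sqrt(heap.top());
  }
  return out;
}
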