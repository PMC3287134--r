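// Maximum-norm (Chebyshev) nearest-neighbour machinery with Theiler
// exclusion, shared by the KSG estimators, the Cao criterion and the
// local constant predictor.  A KD-tree is used for n >= 64 points; below
// that the whole point set is treated as a single leaf (brute force).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct PointSet {
  std::vector<double> x;  // row-major n x m
  int n, m;
  double at(int i, int j) const { return x[(size_t)i * m + j]; }
};

inline double dist_max(const PointSet &P, int i, int j) {
  double d = 0.0;
  const double *a = &P.x[(size_t)i * P.m];
  const double *b = &P.x[(size_t)j * P.m];
  for (int c = 0; c < P.m; ++c) {
    double v = std::fabs(a[c] - b[c]);
    if (v > d) d = v;
  }
  return d;
}

// abandons the scan as soon as the partial distance reaches `cap`
// (the caller must treat any return >= cap as "too far")
inline double dist_max_capped(const PointSet &P, int i, int j, double cap) {
  double d = 0.0;
  const double *a = &P.x[(size_t)i * P.m];
  const double *b = &P.x[(size_t)j * P.m];
  for (int c = 0; c < P.m; ++c) {
    double v = std::fabs(a[c] - b[c]);
    if (v > d) {
      d = v;
      if (d >= cap) return d;
    }
  }
  return d;
}

struct Node {
  int lo, hi;          // range in idx
  int left, right;     // children (-1 for leaf)
  std::vector<double> bmin, bmax;
};

struct KDTree {
  const PointSet *P;
  std::vector<int> idx;
  std::vector<Node> nodes;
  int leaf_size;

  void build(const PointSet &pts, int leaf) {
    P = &pts;
    leaf_size = leaf;
    idx.resize(P->n);
    for (int i = 0; i < P->n; ++i) idx[i] = i;
    nodes.reserve(2 * (P->n / leaf + 2));
    if (P->n > 0) split(0, P->n);
  }

  int split(int lo, int hi) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    Node &nd = nodes.back();
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    nd.bmin.assign(P->m, INF);
    nd.bmax.assign(P->m, -INF);
    for (int i = lo; i < hi; ++i)
      for (int c = 0; c < P->m; ++c) {
        double v = P->at(idx[i], c);
        if (v < nd.bmin[c]) nd.bmin[c] = v;
        if (v > nd.bmax[c]) nd.bmax[c] = v;
      }
    if (hi - lo <= leaf_size) return id;
    // widest dimension
    int dim = 0; double w = -1.0;
    for (int c = 0; c < P->m; ++c) {
      double s = nd.bmax[c] - nd.bmin[c];
      if (s > w) { w = s; dim = c; }
    }
    if (w <= 0.0) return id;  // all points identical: keep as leaf
    int mid = (lo + hi) / 2;
    const PointSet *pp = P;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [pp, dim](int a, int b) { return pp->at(a, dim) < pp->at(b, dim); });
    int l = split(lo, mid);
    int r = split(mid, hi);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  // max-norm gap between query point q (row of P) and node bbox
  double gap(const Node &nd, const double *q) const {
    double g = 0.0;
    for (int c = 0; c < P->m; ++c) {
      double lo = nd.bmin[c] - q[c], hi = q[c] - nd.bmax[c];
      double v = lo > hi ? lo : hi;
      if (v > g) g = v;
    }
    return g;
  }
};

// small insertion-sorted k-best buffer
struct KBest {
  int k, n;
  std::vector<double> d;
  std::vector<int> id;
  KBest(int k_) : k(k_), n(0), d(k_, INF), id(k_, -1) {}
  double worst() const { return n < k ? INF : d[k - 1]; }
  void push(double dist, int j) {
    if (n == k && dist >= d[k - 1]) return;
    int pos = (n < k) ? n : k - 1;
    if (n < k) ++n;
    while (pos > 0 && d[pos - 1] > dist) {
      d[pos] = d[pos - 1]; id[pos] = id[pos - 1];
      --pos;
    }
    d[pos] = dist; id[pos] = j;
  }
};

void knn_query(const KDTree &T, int node, int qi, const int *tidx, int theiler,
               KBest &best) {
  const Node &nd = T.nodes[node];
  const double *q = &T.P->x[(size_t)qi * T.P->m];
  if (T.gap(nd, q) >= best.worst()) return;
  if (nd.left < 0) {
    for (int i = nd.lo; i < nd.hi; ++i) {
      int j = T.idx[i];
      if (std::abs(tidx[qi] - tidx[j]) <= theiler) continue;
      double w = best.worst();
      double d = (w == INF) ? dist_max(*T.P, qi, j)
                            : dist_max_capped(*T.P, qi, j, w);
      if (d < w) best.push(d, j);
    }
    return;
  }
  // visit nearer child first
  double gl = T.gap(T.nodes[nd.left], q), gr = T.gap(T.nodes[nd.right], q);
  if (gl <= gr) {
    knn_query(T, nd.left, qi, tidx, theiler, best);
    knn_query(T, nd.right, qi, tidx, theiler, best);
  } else {
    knn_query(T, nd.right, qi, tidx, theiler, best);
    knn_query(T, nd.left, qi, tidx, theiler, best);
  }
}

void count_query(const KDTree &T, int node, int qi, const int *tidx, int theiler,
                 double r, bool strict, int &cnt) {
  const Node &nd = T.nodes[node];
  const double *q = &T.P->x[(size_t)qi * T.P->m];
  double g = T.gap(nd, q);
  if (strict ? (g >= r) : (g > r)) return;
  if (nd.left < 0) {
    for (int i = nd.lo; i < nd.hi; ++i) {
      int j = T.idx[i];
      if (std::abs(tidx[qi] - tidx[j]) <= theiler) continue;
      double cap = strict ? r : std::nextafter(r, INF);
      double d = dist_max_capped(*T.P, qi, j, cap);
      if (strict ? (d < r) : (d <= r)) ++cnt;
    }
    return;
  }
  count_query(T, nd.left, qi, tidx, theiler, r, strict, cnt);
  count_query(T, nd.right, qi, tidx, theiler, r, strict, cnt);
}

void ball_future_query(const KDTree &T, int node, int qi, const int *tidx,
                       int theiler, double r, const double *fut,
                       double &sum, int &cnt) {
  const Node &nd = T.nodes[node];
  const double *q = &T.P->x[(size_t)qi * T.P->m];
  if (T.gap(nd, q) > r) return;
  if (nd.left < 0) {
    for (int i = nd.lo; i < nd.hi; ++i) {
      int j = T.idx[i];
      if (std::abs(tidx[qi] - tidx[j]) <= theiler) continue;
      if (dist_max_capped(*T.P, qi, j, std::nextafter(r, INF)) <= r) {
        sum += fut[j]; ++cnt;
      }
    }
    return;
  }
  ball_future_query(T, nd.left, qi, tidx, theiler, r, fut, sum, cnt);
  ball_future_query(T, nd.right, qi, tidx, theiler, r, fut, sum, cnt);
}

PointSet to_pointset(const NumericMatrix &X) {
  PointSet P;
  P.n = X.nrow(); P.m = X.ncol();
  P.x.resize((size_t)P.n * P.m);
  for (int i = 0; i < P.n; ++i)
    for (int j = 0; j < P.m; ++j)
      P.x[(size_t)i * P.m + j] = X(i, j);
  return P;
}

int leaf_for(int n) { return n < 64 ? n : 16; }

}  // namespace

// Distance to the k-th nearest admissible neighbour of every point.
// Admissible: |tidx_i - tidx_j| > theiler (this excludes the point itself).
// Returns Inf where fewer than k admissible neighbours exist.
// [[Rcpp::export]]
NumericVector nn_kdist_cpp(NumericMatrix X, int k, int theiler, IntegerVector tidx) {
  PointSet P = to_pointset(X);
  KDTree T; T.build(P, leaf_for(P.n));
  NumericVector out(P.n);
  for (int i = 0; i < P.n; ++i) {
    KBest best(k);
    knn_query(T, 0, i, tidx.begin(), theiler, best);
    out[i] = (best.n < k) ? INF : best.d[k - 1];
  }
  return out;
}

// Index (1-based) of the k-th nearest admissible neighbour, plus its distance.
// [[Rcpp::export]]
List nn_kindex_cpp(NumericMatrix X, int k, int theiler, IntegerVector tidx) {
  PointSet P = to_pointset(X);
  KDTree T; T.build(P, leaf_for(P.n));
  IntegerVector idx(P.n);
  NumericVector dist(P.n);
  for (int i = 0; i < P.n; ++i) {
    KBest best(k);
    knn_query(T, 0, i, tidx.begin(), theiler, best);
    if (best.n < k) { idx[i] = NA_INTEGER; dist[i] = NA_REAL; }
    else { idx[i] = best.id[k - 1] + 1; dist[i] = best.d[k - 1]; }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Number of admissible neighbours within radius r_i of point i
// (strict: distance < r_i; otherwise <=).
// [[Rcpp::export]]
IntegerVector nn_count_cpp(NumericMatrix X, NumericVector radii, int theiler,
                           IntegerVector tidx, bool strict) {
  PointSet P = to_pointset(X);
  KDTree T; T.build(P, leaf_for(P.n));
  IntegerVector out(P.n);
  for (int i = 0; i < P.n; ++i) {
    int cnt = 0;
    count_query(T, 0, i, tidx.begin(), theiler, radii[i], strict, cnt);
    out[i] = cnt;
  }
  return out;
}

// Local constant predictor: mean of the futures of the neighbourhood of
// each point.  mass_mode: the `size` nearest admissible neighbours;
// otherwise all admissible neighbours with distance <= size (Eq. ball).
// Returns the prediction (NaN where the neighbourhood is empty) and the
// neighbourhood size used.
// [[Rcpp::export]]
List lcp_predict_cpp(NumericMatrix X, NumericVector futures, bool mass_mode,
                     double size, int theiler, IntegerVector tidx) {
  PointSet P = to_pointset(X);
  KDTree T; T.build(P, leaf_for(P.n));
  NumericVector pred(P.n);
  IntegerVector nn(P.n);
  for (int i = 0; i < P.n; ++i) {
    double s = 0.0; int c = 0;
    if (mass_mode) {
      int k = (int)size;
      KBest best(k);
      knn_query(T, 0, i, tidx.begin(), theiler, best);
      for (int j = 0; j < best.n; ++j) { s += futures[best.id[j]]; ++c; }
    } else {
      ball_future_query(T, 0, i, tidx.begin(), theiler, size, futures.begin(), s, c);
    }
    nn[i] = c;
    pred[i] = (c > 0) ? s / c : NA_REAL;
  }
  return List::create(_["pred"] = pred, _["n_neigh"] = nn);
}
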