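#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double sqdist(const NumericMatrix& a, int i,
                            const NumericMatrix& b, int j) {
  double dx = a(i, 0) - b(j, 0);
  double dy = a(i, 1) - b(j, 1);
  double dz = a(i, 2) - b(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// Farthest point sampling.  Greedy: each pick maximises the minimum distance
// to all previously selected points; ties broken by lowest index.  Indices
// are 1-based.  Initial min-distance array is +Inf so the start point wins
// nothing but every later comparison is a true minimum.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix coords, int S, int start) {
  int N = coords.nrow();
  IntegerVector out(S);
  std::vector<double> mind(N, R_PosInf);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int s = 1; s < S; ++s) {
    double best = -1.0;
    int besti = -1;
    for (int i = 0; i < N; ++i) {
      double d = sqdist(coords, i, coords, cur);
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > best) {  // strict >: ties keep the lowest index
        best = mind[i];
        besti = i;
      }
    }
    cur = besti;
    out[s] = cur + 1;
  }
  return out;
}

// Ball query: per center, up to K point indices with distance <= radius in
// ascending index order; pad by repeating the nearest qualifying index (a
// geometric choice, so padded groups do not depend on point storage order);
// if the ball is empty, the globally nearest point (ties -> lowest index)
// fills all K slots.
// [[Rcpp::export]]
IntegerMatrix cpp_ball_query(NumericMatrix coords, NumericMatrix centers,
                             double radius, int K) {
  int N = coords.nrow(), S = centers.nrow();
  double r2 = radius * radius;
  IntegerMatrix out(S, K);
  for (int c = 0; c < S; ++c) {
    int found = 0;
    double dmin = R_PosInf;
    int nearest = 0;
    for (int i = 0; i < N; ++i) {
      double d = sqdist(coords, i, centers, c);
      if (d <= r2 && found < K) out(c, found++) = i + 1;
      if (d < dmin) { dmin = d; nearest = i; }  // strict <: ties keep lowest
    }
    for (int k = found; k < K; ++k) out(c, k) = nearest + 1;
  }
  return out;
}

// K nearest neighbours per query row, ascending distance, ties by lowest
// index (stable sort on distance).
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix coords, NumericMatrix queries, int K) {
  int N = coords.nrow(), Q = queries.nrow();
  IntegerMatrix out(Q, K);
  std::vector<double> d(N);
  std::vector<int> idx(N);
  for (int q = 0; q < Q; ++q) {
    for (int i = 0; i < N; ++i) {
      d[i] = sqdist(coords, i, queries, q);
      idx[i] = i;
    }
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return d[a] < d[b]; });
    for (int k = 0; k < K; ++k) out(q, k) = idx[k] + 1;
  }
  return out;
}

// Column-wise max over K consecutive rows per group.  X is (S*K) x C,
// center-major (rows 1..K belong to group 1).  Returns the S x C maxima and
// the (1-based) row index into X attaining each maximum (first attainer).
// [[Rcpp::export]]
List cpp_group_max(NumericMatrix X, int S, int K) {
  int C = X.ncol();
  NumericMatrix mx(S, C);
  IntegerMatrix arg(S, C);
  for (int s = 0; s < S; ++s) {
    int base = s * K;
    for (int c = 0; c < C; ++c) {
      double best = X(base, c);
      int bi = base;
      for (int k = 1; k < K; ++k) {
        double v = X(base + k, c);
        if (v > best) { best = v; bi = base + k; }
      }
      mx(s, c) = best;
      arg(s, c) = bi + 1;
    }
  }
  return List::create(_["max"] = mx, _["argmax"] = arg);
}

// Mask of "true" neighbours for the per-center star graph: first occurrence
// in the row and different from the center's own index (padding duplicates
// and self-entries are dropped before graph construction).
// [[Rcpp::export]]
LogicalMatrix cpp_dedup_mask(IntegerMatrix neigh, IntegerVector centers) {
  int S = neigh.nrow(), K = neigh.ncol();
  LogicalMatrix out(S, K);
  for (int s = 0; s < S; ++s) {
    for (int k = 0; k < K; ++k) {
      int v = neigh(s, k);
      bool keep = (v != centers[s]);
      for (int j = 0; j < k && keep; ++j)
        if (neigh(s, j) == v) keep = false;
      out(s, k) = keep;
    }
  }
  return out;
}
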