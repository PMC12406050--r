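#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// copy an R matrix (n x d, column-major) into point-major storage so each
// point's features are contiguous in the distance loops
static std::vector<double> to_point_major(const NumericMatrix& X) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> out((size_t)n * d);
  for (int j = 0; j < d; ++j) {
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) out[(size_t)i * d + j] = col[i];
  }
  return out;
}

static inline double l1(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += std::fabs(a[j] - b[j]);
  return s;
}

// One run of L1-norm k-means: nearest-centroid assignment with lowest-index
// tie-break, component-wise-median centroid update, until assignments are
// stable or max_iter is reached. init is 1-based row indices of the
// initial centroids.
// [[Rcpp::export]]
List kmeans_l1_run(const NumericMatrix& X, const IntegerVector& init,
                   int max_iter) {
  const int n = X.nrow(), d = X.ncol(), K = init.size();
  const std::vector<double> P = to_point_major(X);
  std::vector<double> C((size_t)K * d);
  for (int k = 0; k < K; ++k)
    std::copy(P.begin() + (size_t)(init[k] - 1) * d,
              P.begin() + (size_t)init[k] * d, C.begin() + (size_t)k * d);
  IntegerVector lab(n, -1);
  int iter = 0;
  bool changed = true;
  std::vector<double> buf;
  while (changed && iter < max_iter) {
    ++iter;
    changed = false;
    for (int i = 0; i < n; ++i) {
      const double* xi = &P[(size_t)i * d];
      double best = R_PosInf;
      int bk = 0;
      for (int k = 0; k < K; ++k) {
        double dist = l1(xi, &C[(size_t)k * d], d);
        if (dist < best) { best = dist; bk = k; }
      }
      if (lab[i] != bk) { lab[i] = bk; changed = true; }
    }
    if (!changed) break;
    for (int k = 0; k < K; ++k) {
      int count = 0;
      for (int i = 0; i < n; ++i) if (lab[i] == k) ++count;
      if (count == 0) {
        // re-seed an empty cluster at the point farthest from its centroid
        double worst = -1.0; int wi = 0;
        for (int i = 0; i < n; ++i) {
          double dist = l1(&P[(size_t)i * d], &C[(size_t)lab[i] * d], d);
          if (dist > worst) { worst = dist; wi = i; }
        }
        std::copy(P.begin() + (size_t)wi * d, P.begin() + (size_t)(wi + 1) * d,
                  C.begin() + (size_t)k * d);
        changed = true;
        continue;
      }
      for (int j = 0; j < d; ++j) {
        buf.clear();
        buf.reserve(count);
        for (int i = 0; i < n; ++i)
          if (lab[i] == k) buf.push_back(P[(size_t)i * d + j]);
        C[k * (size_t)d + j] = median_inplace(buf);
      }
    }
  }
  double cost = 0.0;
  for (int i = 0; i < n; ++i)
    cost += l1(&P[(size_t)i * d], &C[(size_t)lab[i] * d], d);
  NumericMatrix Cm(K, d);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j) Cm(k, j) = C[(size_t)k * d + j];
  return List::create(_["labels"] = lab + 1, _["centroids"] = Cm,
                      _["cost"] = cost, _["iterations"] = iter);
}

// L1 distances from each row of X to each row of C (n x K)
// [[Rcpp::export]]
NumericMatrix l1_dist_to_centroids(const NumericMatrix& X,
                                   const NumericMatrix& C) {
  const int n = X.nrow(), d = X.ncol(), K = C.nrow();
  const std::vector<double> P = to_point_major(X);
  const std::vector<double> Q = to_point_major(C);
  NumericMatrix D(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      D(i, k) = l1(&P[(size_t)i * d], &Q[(size_t)k * d], d);
  return D;
}
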