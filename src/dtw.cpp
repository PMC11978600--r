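#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dependent multivariate DTW: one alignment path shared by all feature
// dimensions, local cost = squared Euclidean distance between the aligned
// feature vectors. Sequences are matrices with rows = time points.

static inline double sqdist_row(const NumericMatrix& a, int i,
                                const NumericMatrix& b, int j) {
  double s = 0.0;
  const int d = a.ncol();
  for (int c = 0; c < d; ++c) {
    const double df = a(i, c) - b(j, c);
    s += df * df;
  }
  return s;
}

// Accumulated-cost matrix under the symmetric step pattern
// (i-1,j), (i,j-1), (i-1,j-1), boundary-anchored at both ends.
static std::vector<double> dtw_acc(const NumericMatrix& a,
                                   const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow();
  std::vector<double> D((size_t)n * m);
  D[0] = sqdist_row(a, 0, b, 0);
  for (int j = 1; j < m; ++j) D[j] = D[j - 1] + sqdist_row(a, 0, b, j);
  for (int i = 1; i < n; ++i) {
    D[(size_t)i * m] = D[(size_t)(i - 1) * m] + sqdist_row(a, i, b, 0);
    for (int j = 1; j < m; ++j) {
      const double up   = D[(size_t)(i - 1) * m + j];
      const double left = D[(size_t)i * m + j - 1];
      const double diag = D[(size_t)(i - 1) * m + j - 1];
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      D[(size_t)i * m + j] = best + sqdist_row(a, i, b, j);
    }
  }
  return D;
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.ncol() != b.ncol()) stop("feature dimensions differ");
  if (a.nrow() == 0 || b.nrow() == 0) stop("empty trajectory");
  std::vector<double> D = dtw_acc(a, b);
  return std::sqrt(D[(size_t)a.nrow() * b.nrow() - 1]);
}

// Optimal warping path, backtracked with deterministic tie-breaking
// (diagonal preferred, then the vertical step). 1-based indices.
// [[Rcpp::export]]
IntegerMatrix dtw_path_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.ncol() != b.ncol()) stop("feature dimensions differ");
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("empty trajectory");
  std::vector<double> D = dtw_acc(a, b);
  std::vector<std::pair<int, int> > rev;
  int i = n - 1, j = m - 1;
  rev.push_back(std::make_pair(i, j));
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      const double diag = D[(size_t)(i - 1) * m + j - 1];
      const double up   = D[(size_t)(i - 1) * m + j];
      const double left = D[(size_t)i * m + j - 1];
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    rev.push_back(std::make_pair(i, j));
  }
  const int L = (int)rev.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = rev[L - 1 - k].first + 1;
    path(k, 1) = rev[L - 1 - k].second + 1;
  }
  return path;
}

// Distance matrix between a list of trajectories and a list of centroids.
// [[Rcpp::export]]
NumericMatrix dtw_cross_dist_cpp(List A, List B) {
  const int n = A.size(), k = B.size();
  NumericMatrix out(n, k);
  std::vector<NumericMatrix> bs;
  bs.reserve(k);
  for (int j = 0; j < k; ++j) bs.push_back(as<NumericMatrix>(B[j]));
  for (int i = 0; i < n; ++i) {
    NumericMatrix ai = as<NumericMatrix>(A[i]);
    for (int j = 0; j < k; ++j) {
      std::vector<double> D = dtw_acc(ai, bs[j]);
      out(i, j) = std::sqrt(D[(size_t)ai.nrow() * bs[j].nrow() - 1]);
    }
  }
  return out;
}

// One DTW barycenter averaging sweep: align every member to the current
// centroid, replace each centroid point by the mean of the member points
// mapped onto it. Returns the updated centroid and the objective (sum of
// squared DTW distances) evaluated at the *incoming* centroid.
// [[Rcpp::export]]
List dba_update_cpp(List members, NumericMatrix centroid) {
  const int L = centroid.nrow(), d = centroid.ncol();
  NumericMatrix acc(L, d);
  NumericVector cnt(L);
  double obj = 0.0;
  for (int s = 0; s < members.size(); ++s) {
    NumericMatrix tr = as<NumericMatrix>(members[s]);
    if (tr.ncol() != d) stop("feature dimensions differ");
    std::vector<double> D = dtw_acc(tr, centroid);
    obj += D[(size_t)tr.nrow() * L - 1];
    // backtrack (same tie-break as dtw_path_cpp)
    int i = tr.nrow() - 1, j = L - 1;
    for (;;) {
      for (int c = 0; c < d; ++c) acc(j, c) += tr(i, c);
      cnt[j] += 1.0;
      if (i == 0 && j == 0) break;
      if (i == 0) { --j; }
      else if (j == 0) { --i; }
      else {
        const double diag = D[(size_t)(i - 1) * L + j - 1];
        const double up   = D[(size_t)(i - 1) * L + j];
        const double left = D[(size_t)i * L + j - 1];
        if (diag <= up && diag <= left) { --i; --j; }
        else if (up <= left) { --i; }
        else { --j; }
      }
    }
  }
  NumericMatrix out(L, d);
  for (int j = 0; j < L; ++j) {
    if (cnt[j] > 0.0) {
      for (int c = 0; c < d; ++c) out(j, c) = acc(j, c) / cnt[j];
    } else {
      for (int c = 0; c < d; ++c) out(j, c) = centroid(j, c);
    }
  }
  return List::create(_["centroid"] = out, _["objective"] = obj);
}
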