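#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// False-nearest-neighbour count for a single embedding dimension m.
// Points are restricted to those whose (m+1)-th delay coordinate exists so
// the distance-ratio test is defined. The nearest neighbour excludes pairs
// within the Theiler window; ties resolve to the smallest index.
// [[Rcpp::export]]
List fnn_count_cpp(NumericVector x, int tau, int m, double R, int theiler) {
  const int N = x.size();
  const int M = N - m * tau;
  if (M < 2) return List::create(_["n_false"] = 0, _["n_total"] = 0);
  int nfalse = 0, ntotal = 0;
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = x[i + k * tau] - x[j + k * tau];
        d += diff * diff;
        if (d >= best) break;
      }
      if (d < best) { best = d; bj = j; }
    }
    if (bj < 0) continue;
    const double dm = std::sqrt(best);
    const double extra = std::fabs(x[i + m * tau] - x[bj + m * tau]);
    ++ntotal;
    if (dm == 0.0) {
      if (extra > 0.0) ++nfalse;       // coincident in dim m, split in m+1
    } else if (extra / dm > R) {
      ++nfalse;
    }
  }
  return List::create(_["n_false"] = nfalse, _["n_total"] = ntotal);
}

// Nearest-neighbour divergence bookkeeping for the largest-Lyapunov-exponent
// estimate: for every point find its nearest neighbour outside the Theiler
// window, then follow each pair forward, accumulating log(d_k / d_0).
// [[Rcpp::export]]
List divergence_cpp(NumericMatrix emb, int theiler, int max_steps) {
  const int M = emb.nrow(), m = emb.ncol();
  std::vector<int> nn(M, -1);
  std::vector<double> d0(M, 0.0);
  int admissible = 0, zero_pairs = 0;
  for (int i = 0; i < M; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = emb(i, k) - emb(j, k);
        d += diff * diff;
        if (d >= best) break;
      }
      if (d < best) { best = d; bj = j; }
    }
    if (bj < 0) continue;
    ++admissible;
    const double d = std::sqrt(best);
    if (d == 0.0) {
      ++zero_pairs;                    // unusable pair: zero initial distance
    } else {
      nn[i] = bj;
      d0[i] = d;
    }
  }
  NumericVector sums(max_steps + 1);
  IntegerVector counts(max_steps + 1);
  for (int i = 0; i < M; ++i) {
    if (nn[i] < 0) continue;
    const int j = nn[i];
    for (int k = 0; k <= max_steps; ++k) {
      if (i + k >= M || j + k >= M) break;
      double d = 0.0;
      for (int c = 0; c < m; ++c) {
        const double diff = emb(i + k, c) - emb(j + k, c);
        d += diff * diff;
      }
      d = std::sqrt(d);
      if (d > 0.0) {
        sums[k] += std::log(d / d0[i]);
        ++counts[k];
      }
    }
  }
  return List::create(_["sum_log"] = sums, _["count"] = counts,
                      _["n_admissible"] = admissible,
                      _["n_zero"] = zero_pairs);
}
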