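#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

#if defined(__GNUC__) || defined(__clang__)
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// Classic unnormalized DTW: min over warping paths of the sum of |x_i - y_j|,
// steps (i-1,j), (i,j-1), (i-1,j-1), each cell's local cost counted once.
// Rolling one-row DP with an explicit diagonal register; ws is a caller-owned
// workspace of length >= q.
static double dtw_core(const double* RESTRICT x, int p,
                       const double* RESTRICT y, int q,
                       double* RESTRICT row) {
  double c = std::fabs(x[0] - y[0]);
  row[0] = c;
  for (int j = 1; j < q; ++j) row[j] = row[j - 1] + std::fabs(x[0] - y[j]);
  for (int i = 1; i < p; ++i) {
    const double xi = x[i];
    double diag = row[0];                   // acc[i-1][j-1]
    row[0] = row[0] + std::fabs(xi - y[0]); // acc[i][0]
    double left = row[0];
    for (int j = 1; j < q; ++j) {
      const double up = row[j];
      double best = diag < up ? diag : up;
      if (left < best) best = left;
      left = best + std::fabs(xi - y[j]);
      row[j] = left;
      diag = up;
    }
  }
  return row[q - 1];
}

// Discrete Frechet: min over couplings of the max node distance; DP cell
// value = max(local distance, min of the three predecessors).
static double frechet_core(const double* RESTRICT x, int p,
                           const double* RESTRICT y, int q,
                           double* RESTRICT row) {
  double c = std::fabs(x[0] - y[0]);
  row[0] = c;
  for (int j = 1; j < q; ++j) {
    c = std::fabs(x[0] - y[j]);
    row[j] = row[j - 1] > c ? row[j - 1] : c;
  }
  for (int i = 1; i < p; ++i) {
    const double xi = x[i];
    double diag = row[0];
    c = std::fabs(xi - y[0]);
    row[0] = row[0] > c ? row[0] : c;
    double left = row[0];
    for (int j = 1; j < q; ++j) {
      const double up = row[j];
      double best = diag < up ? diag : up;
      if (left < best) best = left;
      c = std::fabs(xi - y[j]);
      left = best > c ? best : c;
      row[j] = left;
      diag = up;
    }
  }
  return row[q - 1];
}

// [[Rcpp::export]]
double cpp_dtw(NumericVector x, NumericVector y) {
  std::vector<double> ws(y.size());
  return dtw_core(x.begin(), x.size(), y.begin(), y.size(), ws.data());
}

// [[Rcpp::export]]
double cpp_frechet(NumericVector x, NumericVector y) {
  std::vector<double> ws(y.size());
  return frechet_core(x.begin(), x.size(), y.begin(), y.size(), ws.data());
}

// metric: 0 = dtw, 1 = frechet, 2 = euclidean (equal lengths enforced in R)
// [[Rcpp::export]]
NumericMatrix cpp_pairwise(List series, int metric) {
  int n = series.size();
  std::vector<const double*> ptr(n);
  std::vector<int> len(n);
  std::vector<NumericVector> keep(n);  // hold refs so pointers stay valid
  int maxlen = 0;
  for (int i = 0; i < n; ++i) {
    keep[i] = as<NumericVector>(series[i]);
    ptr[i] = keep[i].begin();
    len[i] = keep[i].size();
    if (len[i] > maxlen) maxlen = len[i];
  }
  std::vector<double> ws(maxlen);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d;
      if (metric == 0) {
        d = dtw_core(ptr[i], len[i], ptr[j], len[j], ws.data());
      } else if (metric == 1) {
        d = frechet_core(ptr[i], len[i], ptr[j], len[j], ws.data());
      } else {
        double s = 0.0;
        for (int k = 0; k < len[i]; ++k) {
          double diff = ptr[i][k] - ptr[j][k];
          s += diff * diff;
        }
        d = std::sqrt(s);
      }
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
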