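#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ultrametric violation penalty over a symmetric matrix U:
//   Phi(U) = sum over unordered pairs {i,k} and intermediates j of
//            (u_ik - max(u_ij, u_jk))^2 whenever u_ik > max(u_ij, u_jk),
// with its gradient w.r.t. the full symmetric matrix (each unordered pair's
// derivative is accumulated on both (i,k) and (k,i) so that the caller can
// read the upper triangle directly).
// [[Rcpp::export]]
List cpp_ultra_penalty(NumericMatrix U) {
  int n = U.nrow();
  NumericMatrix grad(n, n);
  double phi = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        if (j == i || j == k) continue;
        double uij = U(i, j), ujk = U(j, k);
        double mx = (uij > ujk) ? uij : ujk;
        double v = uik - mx;
        if (v > 0.0) {
          phi += v * v;
          grad(i, k) += 2.0 * v;
          grad(k, i) += 2.0 * v;
          if (uij > ujk) {
            grad(i, j) -= 2.0 * v;
            grad(j, i) -= 2.0 * v;
          } else {
            grad(j, k) -= 2.0 * v;
            grad(k, j) -= 2.0 * v;
          }
        }
      }
    }
  }
  return List::create(_["phi"] = phi, _["grad"] = grad);
}

// Helpers for the SUMT inner minimization. The free variables are the
// upper-triangle entries of U in R's column-major upper.tri order
// ((1,2),(1,3),(2,3),(1,4),...). The least-squares part is expanded as
//   L(U) = wtot * sum u^2 - 2 * sum u * sumwd + cst,
// where sumwd is the weighted sum of the descriptor matrices (upper
// triangle) and cst collects the data-only terms.

static void fill_sym(const NumericVector& v, Rcpp::NumericMatrix& U, int n) {
  int idx = 0;
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      U(i, j) = v[idx];
      U(j, i) = v[idx];
      ++idx;
    }
  }
}

// [[Rcpp::export]]
double cpp_sumt_obj(NumericVector v, NumericVector sumwd, double wtot,
                    double cst, double r, int n) {
  NumericMatrix U(n, n);
  fill_sym(v, U, n);
  double L = cst;
  for (int t = 0; t < v.size(); ++t) L += wtot * v[t] * v[t] - 2.0 * v[t] * sumwd[t];
  double phi = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        if (j == i || j == k) continue;
        double uij = U(i, j), ujk = U(j, k);
        double mx = (uij > ujk) ? uij : ujk;
        double d = uik - mx;
        if (d > 0.0) phi += d * d;
      }
    }
  }
  return L + r * phi;
}

// [[Rcpp::export]]
NumericVector cpp_sumt_grad(NumericVector v, NumericVector sumwd, double wtot,
                            double r, int n) {
  NumericMatrix U(n, n);
  fill_sym(v, U, n);
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        if (j == i || j == k) continue;
        double uij = U(i, j), ujk = U(j, k);
        double mx = (uij > ujk) ? uij : ujk;
        double d = uik - mx;
        if (d > 0.0) {
          G(i, k) += 2.0 * d;
          if (uij > ujk) {
            if (i < j) G(i, j) -= 2.0 * d; else G(j, i) -= 2.0 * d;
          } else {
            if (j < k) G(j, k) -= 2.0 * d; else G(k, j) -= 2.0 * d;
          }
        }
      }
    }
  }
  NumericVector out(v.size());
  int idx = 0;
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      out[idx] = 2.0 * wtot * v[idx] - 2.0 * sumwd[idx] + r * G(i, j);
      ++idx;
    }
  }
  return out;
}

// Worst ultrametric violation: max over triples of u_ik - max(u_ij, u_jk),
// with the achieving triple (1-based, as (i, j, k) with j the intermediate).
// [[Rcpp::export]]
List cpp_worst_violation(NumericMatrix U) {
  int n = U.nrow();
  double worst = R_NegInf;
  int wi = 0, wj = 0, wk = 0;
  if (n < 3) {
    return List::create(_["violation"] = 0.0,
                        _["triple"] = IntegerVector::create(0, 0, 0));
  }
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        if (j == i || j == k) continue;
        double uij = U(i, j), ujk = U(j, k);
        double mx = (uij > ujk) ? uij : ujk;
        if (uik - mx > worst) {
          worst = uik - mx;
          wi = i; wj = j; wk = k;
        }
      }
    }
  }
  return List::create(
      _["violation"] = worst,
      _["triple"] = IntegerVector::create(wi + 1, wj + 1, wk + 1));
}
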