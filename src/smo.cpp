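#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// RBF kernel matrix between rows of A (na x p) and B (nb x p).
static void rbf_cross(const NumericMatrix& A, const NumericMatrix& B,
                      double gamma, std::vector<double>& K) {
  const int na = A.nrow(), nb = B.nrow(), p = A.ncol();
  K.assign((size_t)na * nb, 0.0);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double d = 0.0;
      for (int c = 0; c < p; ++c) {
        const double t = A(i, c) - B(j, c);
        d += t * t;
      }
      K[(size_t)i * nb + j] = std::exp(-gamma * d);
    }
  }
}

// Soft-margin SVM dual solved by SMO with first-order (maximal violating
// pair) working-set selection, as in LibSVM's WSS1. The full kernel matrix
// is precomputed; intended for n up to a few thousand.
// [[Rcpp::export]]
List smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
               double eps = 1e-3, int max_iter = 0) {
  const int n = X.nrow(), p = X.ncol();
  if (max_iter <= 0) max_iter = std::max(10000000 / std::max(n, 1), 100 * n);
  std::vector<double> K;
  {
    // symmetric self-kernel
    K.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i) {
      K[(size_t)i * n + i] = 1.0;
      for (int j = i + 1; j < n; ++j) {
        double d = 0.0;
        for (int c = 0; c < p; ++c) {
          const double t = X(i, c) - X(j, c);
          d += t * t;
        }
        const double k = std::exp(-gamma * d);
        K[(size_t)i * n + j] = k;
        K[(size_t)j * n + i] = k;
      }
    }
  }
  std::vector<double> alpha(n, 0.0);
  // g_i = d f / d alpha_i = y_i * F_i - 1, where F_i = sum_j alpha_j y_j K_ij
  std::vector<double> g(n, -1.0);
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: i in I_up maximizing -y g, j in I_low minimizing
    int ii = -1, jj = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * g[t];
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > m_up) { m_up = v; ii = t; }
      if (low && v < m_low) { m_low = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || m_up - m_low < eps) break;
    const double Kii = K[(size_t)ii * n + ii], Kjj = K[(size_t)jj * n + jj],
                 Kij = K[(size_t)ii * n + jj];
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 1e-12) quad = 1e-12;
    // direction: alpha_i += y_i d, alpha_j -= y_j d
    double d = -(y[ii] * g[ii] - y[jj] * g[jj]) / quad;
    // box constraints on d
    double lo = -std::numeric_limits<double>::infinity();
    double hi = std::numeric_limits<double>::infinity();
    if (y[ii] > 0) { lo = std::max(lo, -alpha[ii]); hi = std::min(hi, C - alpha[ii]); }
    else           { lo = std::max(lo, alpha[ii] - C); hi = std::min(hi, alpha[ii]); }
    if (y[jj] > 0) { lo = std::max(lo, alpha[jj] - C); hi = std::min(hi, alpha[jj]); }
    else           { lo = std::max(lo, -alpha[jj]); hi = std::min(hi, C - alpha[jj]); }
    if (d < lo) d = lo;
    if (d > hi) d = hi;
    if (d == 0.0) break;
    const double dai = y[ii] * d;   // change in alpha_i
    const double daj = -y[jj] * d;  // change in alpha_j
    alpha[ii] += dai;
    alpha[jj] += daj;
    const double ci = y[ii] * dai, cj = y[jj] * daj;
    const double* Ki = &K[(size_t)ii * n];
    const double* Kj = &K[(size_t)jj * n];
    for (int t = 0; t < n; ++t) {
      g[t] += y[t] * (Ki[t] * ci + Kj[t] * cj);
    }
  }
  // b from the violation bounds: decision f(x) = sum alpha_i y_i K(x, x_i) + b
  double b = (m_up + m_low) / 2.0;
  if (!std::isfinite(b)) b = 0.0;
  NumericVector av(alpha.begin(), alpha.end());
  return List::create(_["alpha"] = av, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}

// Decision values sum_i coef_i K(x, sv_i) + b for rows of Xnew;
// coef_i = alpha_i * y_i over the support vectors.
// [[Rcpp::export]]
NumericVector rbf_decision(NumericMatrix SV, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int ns = SV.nrow();
  const int nn = Xnew.nrow();
  std::vector<double> K;
  rbf_cross(Xnew, SV, gamma, K);
  NumericVector out(nn);
  for (int i = 0; i < nn; ++i) {
    double s = b;
    for (int j = 0; j < ns; ++j) s += coef[j] * K[(size_t)i * ns + j];
    out[i] = s;
  }
  return out;
}
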