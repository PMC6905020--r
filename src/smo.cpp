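#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dual SVC solver: minimize 1/2 a'Qa - e'a with Q = yy' .* K,
// subject to y'a = 0, 0 <= a <= C. Sequential minimal optimization on the
// maximal-violating pair (first-order working-set selection); the
// two-variable subproblem is solved analytically and clipped to the box.
// Stops when the KKT gap m(a) - M(a) drops below eps.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double eps,
               int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length mismatch");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // grad_t = sum_s a_s y_s y_t K_st - 1

  int iter = 0;
  double gap = R_PosInf;
  for (; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double up_max = -1e300, low_min = 1e300;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > up_max)  { up_max = v;  i = t; }
      if (low && v < low_min) { low_min = v; j = t; }
    }
    gap = up_max - low_min;
    if (i < 0 || j < 0 || gap < eps) break;

    double a2 = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a2 <= 0) a2 = 1e-12;
    double d = gap / a2;
    const double bound_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double bound_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    d = std::min(d, std::min(bound_i, bound_j));

    const double dai = y[i] * d;   // change in alpha_i
    const double daj = -y[j] * d;  // change in alpha_j
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (dai * y[i] * K(i, t) + daj * y[j] * K(j, t));
  }

  // bias: mean of y_t - G_t over free support vectors; midpoint of the
  // violating-pair bounds when no multiplier is strictly inside the box.
  double bsum = 0.0;
  int nfree = 0;
  double up_max = -1e300, low_min = 1e300;
  const double tolC = 1e-8 * C;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * grad[t];  // = y_t - G_t
    const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up && v > up_max)   up_max = v;
    if (low && v < low_min) low_min = v;
    if (alpha[t] > tolC && alpha[t] < C - tolC) { bsum += v; ++nfree; }
  }
  const double b = (nfree > 0) ? bsum / nfree : 0.5 * (up_max + low_min);

  // dual objective (maximization form): sum a - 1/2 sum_t a_t y_t G_t
  double obj = 0.0;
  for (int t = 0; t < n; ++t) {
    const double G = y[t] * (grad[t] + 1.0);
    obj += alpha[t] - 0.5 * alpha[t] * y[t] * G;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["converged"] = (gap < eps));
}
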