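#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Recursive least squares with forgetting factor (Kalman variable-parameter
// regression for one target series). Phi is T' x m (rows are regressor
// vectors), y length T'. State: coefficient vector x (init 0) with
// covariance P = kappa * I. Returns the coefficient trajectory (T' x m)
// and the recursive prediction-error variance estimate.
// [[Rcpp::export(name = ".kalman_rls_cpp")]]
List kalman_rls_cpp(NumericMatrix Phi, NumericVector y, double forgetting,
                    double kappa) {
  const int T = Phi.nrow(), m = Phi.ncol();
  NumericMatrix X(T, m);
  std::vector<double> x(m, 0.0), Pphi(m);
  std::vector<double> P(m * m, 0.0);
  for (int i = 0; i < m; ++i) P[i * m + i] = kappa;
  double s2 = 0.0;
  NumericVector errv(T);
  for (int t = 0; t < T; ++t) {
    // P <- P / lambda
    const double il = 1.0 / forgetting;
    for (int i = 0; i < m * m; ++i) P[i] *= il;
    // Pphi = P phi ; denom = 1 + phi' P phi
    double denom = 1.0;
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += P[i * m + j] * Phi(t, j);
      Pphi[i] = s;
    }
    for (int i = 0; i < m; ++i) denom += Phi(t, i) * Pphi[i];
    // innovation
    double pred = 0.0;
    for (int i = 0; i < m; ++i) pred += Phi(t, i) * x[i];
    const double err = y[t] - pred;
    errv[t] = err;
    s2 += (err * err - s2) / (t + 1.0);
    // x <- x + K err with K = Pphi / denom
    for (int i = 0; i < m; ++i) x[i] += Pphi[i] * err / denom;
    // P <- P - K (phi' P) = P - Pphi Pphi' / denom  (P symmetric)
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j)
        P[i * m + j] -= Pphi[i] * Pphi[j] / denom;
    for (int i = 0; i < m; ++i) {
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e8)
        stop("state estimate blew up at t = %d", t + 1);
      X(t, i) = x[i];
    }
  }
  return List::create(_["coef"] = X, _["pe_var"] = s2, _["err"] = errv);
}
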