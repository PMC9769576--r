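#include <Rcpp.h>
using namespace Rcpp;

// Breslow partial log-likelihood, per-observation gradient and diagonal
// Hessian in the linear predictor, for data pre-sorted by ascending time.
// grad_i = delta_i - exp(eta_i) * A_i,  A_i = sum_{u <= t_i} d_u / D_u
// hess_i = exp(eta_i) * A_i - exp(2 eta_i) * B_i,  B_i likewise with D_u^2
// [[Rcpp::export]]
List cox_derivs_sorted(const NumericVector& time, const NumericVector& event,
                       const NumericVector& eta) {
  const int n = time.size();
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = std::exp(eta[i]);
  std::vector<double> r0(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) r0[i] = r0[i + 1] + e[i];
  double ll = 0.0, cumA = 0.0, cumB = 0.0;
  NumericVector grad(n), hess(n);
  int i = 0;
  while (i < n) {
    int j = i, d = 0;
    while (j < n && time[j] == time[i]) {
      if (event[j] == 1.0) { ++d; ll += eta[j]; }
      ++j;
    }
    if (d > 0) {
      double D = r0[i];
      ll -= d * std::log(D);
      cumA += d / D;
      cumB += d / (D * D);
    }
    for (int k = i; k < j; ++k) {
      grad[k] = (event[k] == 1.0 ? 1.0 : 0.0) - e[k] * cumA;
      hess[k] = e[k] * cumA - e[k] * e[k] * cumB;
    }
    i = j;
  }
  return List::create(_["loglik"] = ll, _["grad"] = grad,
                      _["hess_diag"] = hess);
}
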