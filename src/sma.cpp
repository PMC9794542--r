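#include <Rcpp.h>
#include "sma.h"
using namespace Rcpp;

static SmaParams as_sma(const NumericVector &p) {
  SmaParams q;
  q.EA = p["E_A"]; q.EM = p["E_M"];
  q.sSL = p["sig_SL"]; q.sEL = p["sig_EL"];
  q.sSU = p["sig_SU"]; q.sEU = p["sig_EU"];
  q.epsL = p["eps_L"]; q.alpha = p["alpha"];
  return q;
}

// [[Rcpp::export]]
List sma_update_cpp(double eps_new, double xi, double dir, NumericVector params) {
  SmaParams p = as_sma(params);
  double sig = sma_point(eps_new, xi, dir, p);
  return List::create(_["sig"] = sig, _["xi"] = xi, _["dir"] = dir);
}

// Drive a single material point through a strain path.
// [[Rcpp::export]]
List sma_sweep_cpp(NumericVector eps, NumericVector params,
                   double xi0 = 0.0, double dir0 = 1.0) {
  SmaParams p = as_sma(params);
  int n = eps.size();
  NumericVector sig(n), xi(n);
  double x = xi0, d = dir0;
  for (int i = 0; i < n; ++i) {
    sig[i] = sma_point(eps[i], x, d, p);
    xi[i] = x;
  }
  return List::create(_["sig"] = sig, _["xi"] = xi, _["dir"] = d);
}

// Drive many independent fibres (columns) through strain histories (rows).
// [[Rcpp::export]]
List sma_sweep_multi_cpp(NumericMatrix eps, NumericVector params) {
  SmaParams p = as_sma(params);
  int n = eps.nrow(), m = eps.ncol();
  NumericMatrix sig(n, m), xi(n, m);
  for (int j = 0; j < m; ++j) {
    double x = 0.0, d = 1.0;
    for (int i = 0; i < n; ++i) {
      sig(i, j) = sma_point(eps(i, j), x, d, p);
      xi(i, j) = x;
    }
  }
  return List::create(_["sig"] = sig, _["xi"] = xi);
}
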