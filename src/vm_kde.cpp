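#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// von Mises kernel density evaluation.
//
// density(t) = mean_i exp(kappa * (cos(t - x_i) - 1)) / (2*pi*I0e(kappa))
// where I0e is the exponentially scaled modified Bessel function
// I0(kappa) * exp(-kappa), passed in from R (base besselI handles the
// scaling, avoiding overflow at large kernel concentrations).

// [[Rcpp::export]]
NumericVector cpp_vm_kde_eval(NumericVector t_eval, NumericVector sample,
                              double kappa, double i0e_kappa) {
  const R_xlen_t m = t_eval.size(), n = sample.size();
  if (n < 1) stop("empty sample");
  const double norm = 2.0 * M_PI * i0e_kappa * n;
  // cos(t - s) = cos t cos s + sin t sin s with centers precomputed
  std::vector<double> cs(n), sn(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    cs[i] = std::cos(sample[i]);
    sn[i] = std::sin(sample[i]);
  }
  NumericVector out(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    const double ct = std::cos(t_eval[k]), st = std::sin(t_eval[k]);
    double acc = 0.0;
    for (R_xlen_t i = 0; i < n; ++i)
      acc += std::exp(kappa * (ct * cs[i] + st * sn[i] - 1.0));
    out[k] = acc / norm;
  }
  return out;
}
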