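// In-place Adam update over a flat list of parameter arrays. The params,
// first- and second-moment lists are mutated directly; the caller owns
// them exclusively during training (the trained networks are rebuilt from
// fresh copies when training finishes).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".adam_step_cpp")]]
void adam_step_cpp(List params, List grads, List m, List v, int t,
                   double lr, double beta1, double beta2, double eps) {
  const double c1 = 1.0 - std::pow(beta1, (double)t);
  const double c2 = 1.0 - std::pow(beta2, (double)t);
  const int np = params.size();
  for (int k = 0; k < np; ++k) {
    NumericVector p = params[k];
    NumericVector g = grads[k];
    NumericVector mk = m[k];
    NumericVector vk = v[k];
    const R_xlen_t n = p.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = g[i];
      mk[i] = beta1 * mk[i] + (1.0 - beta1) * gi;
      vk[i] = beta2 * vk[i] + (1.0 - beta2) * gi * gi;
      p[i] -= lr * (mk[i] / c1) / (std::sqrt(vk[i] / c2) + eps);
    }
  }
}
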