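// Hot-path kernels for ZINB training: the mean negative log-likelihood and
// its analytic gradients w.r.t. (mu, theta, pi). Parameters arrive already
// clipped inside their open domains, so every log below is finite.
#include <Rcpp.h>
using namespace Rcpp;

// For integer x, digamma(x + th) - digamma(th) telescopes to
// sum_{j=0}^{x-1} 1/(th + j); likewise lgamma(x + th) - lgamma(th) to
// sum log(th + j). The explicit sums are much cheaper than two special-
// function calls for the small counts that dominate scRNA-seq matrices.
static inline double digamma_diff(double x, double th) {
  if (x < 64.0 && x == std::floor(x)) {
    double s = 0.0;
    for (int j = 0; j < (int)x; ++j) s += 1.0 / (th + j);
    return s;
  }
  return R::digamma(x + th) - R::digamma(th);
}

static inline double lgamma_diff(double x, double th) {
  if (x < 64.0 && x == std::floor(x)) {
    double s = 0.0;
    for (int j = 0; j < (int)x; ++j) s += std::log(th + j);
    return s;
  }
  return R::lgammafn(x + th) - R::lgammafn(th);
}

// [[Rcpp::export(name = ".zinb_nll_cpp")]]
double zinb_nll_cpp(NumericVector x, NumericVector pi, NumericVector mu,
                    NumericVector theta, NumericVector w) {
  const R_xlen_t n = x.size();
  double acc = 0.0, wsum = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double th = theta[i], m = mu[i], p = pi[i], wi = w[i];
    if (wi == 0.0) continue;
    const double tm = th + m;
    const double A = std::log(th / tm);
    double ll;
    if (x[i] > 0.0) {
      ll = std::log1p(-p) + lgamma_diff(x[i], th) - R::lgammafn(x[i] + 1.0)
         + th * A + x[i] * (std::log(m) - std::log(tm));
    } else {
      ll = std::log(p + (1.0 - p) * std::exp(th * A));
    }
    acc += wi * ll;
    wsum += wi;
  }
  return wsum > 0.0 ? -acc / wsum : 0.0;
}

// [[Rcpp::export(name = ".zinb_grad_cpp")]]
List zinb_grad_cpp(NumericVector x, NumericVector pi, NumericVector mu,
                   NumericVector theta) {
  const R_xlen_t n = x.size();
  NumericVector dmu(n), dth(n), dpi(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double th = theta[i], m = mu[i], p = pi[i];
    const double tm = th + m;
    const double A = std::log(th / tm);
    if (x[i] > 0.0) {
      dmu[i] = x[i] / m - (x[i] + th) / tm;
      dth[i] = digamma_diff(x[i], th) + A + (m - x[i]) / tm;
      dpi[i] = -1.0 / (1.0 - p);
    } else {
      const double nb0 = std::exp(th * A);
      const double den = p + (1.0 - p) * nb0;
      dmu[i] = -(1.0 - p) * nb0 * th / tm / den;
      dth[i] = (1.0 - p) * nb0 * (A + m / tm) / den;
      dpi[i] = (1.0 - nb0) / den;
    }
  }
  return List::create(_["dmu"] = dmu, _["dtheta"] = dth, _["dpi"] = dpi);
}
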