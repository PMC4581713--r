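#include <Rcpp.h>
using namespace Rcpp;

// Gonen-Heller concordance probability from Cox linear predictors.
// K = 2/(n(n-1)) * sum_{i<j} [ I(d<0)/(1+exp(d)) + I(d>0)/(1+exp(-d)) ],
// d = lp_i - lp_j; both indicator branches equal 1/(1+exp(-|d|)).  Pairs
// with d == 0 contribute 0.5 (exchangeable pair), so a constant predictor
// yields exactly 0.5.  Row sums are accumulated in double and totalled in
// long double to keep O(n^2) summation error negligible.
// [[Rcpp::export]]
double gonen_heller_cpp(NumericVector lp) {
  const R_xlen_t n = lp.size();
  if (n < 2) stop("need at least 2 subjects");
  long double total = 0.0L;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const double li = lp[i];
    double row = 0.0;
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double d = li - lp[j];
      row += (d == 0.0) ? 0.5 : 1.0 / (1.0 + std::exp(-std::fabs(d)));
    }
    total += row;
  }
  const long double npairs = (long double)n * (n - 1) / 2.0L;
  return (double)(total / npairs);
}
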