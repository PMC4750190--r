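#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Sliding-window PWM score: sum of per-column scores for every window start.
// seq_idx holds bases coded 1..4 (NA for N); windows touching an N score NaN.
// Column-major accumulation with a per-column lookup keeps the inner loop
// branch-free.
// [[Rcpp::export(name = ".window_scores_cpp")]]
NumericVector window_scores_cpp(IntegerVector seq_idx, NumericMatrix M) {
  const int w = M.ncol();
  const int L = seq_idx.size();
  const int n = L - w + 1;
  if (n < 1) return NumericVector(0);
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) {
    const int b = seq_idx[i];
    s[i] = (b == NA_INTEGER) ? 0 : b;
  }
  NumericVector out(n);
  double* o = REAL(out);
  const double nan = std::numeric_limits<double>::quiet_NaN();
  for (int j = 0; j < w; ++j) {
    const double lut[5] = {nan, M(0, j), M(1, j), M(2, j), M(3, j)};
    const int* sj = s.data() + j;
    for (int i = 0; i < n; ++i) o[i] += lut[sj[i]];
  }
  return out;
}
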