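#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filtering of every column of X, with the
// initial filter state set to zi * X(0, col) (the standard choice that
// removes the startup transient for step-like inputs).
// [[Rcpp::export(name = ".lfilter_mat")]]
NumericMatrix lfilter_mat(NumericVector b, NumericVector a, NumericMatrix X,
                          NumericVector zi) {
  const int nt = b.size();       // b and a padded to equal length, a[0] == 1
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix Y(n, m);
  std::vector<double> z(nt - 1);
  for (int c = 0; c < m; ++c) {
    for (int j = 0; j < nt - 1; ++j) z[j] = zi[j] * X(0, c);
    for (int i = 0; i < n; ++i) {
      double x = X(i, c);
      double y = b[0] * x + z[0];
      for (int j = 0; j < nt - 2; ++j)
        z[j] = b[j + 1] * x + z[j + 1] - a[j + 1] * y;
      z[nt - 2] = b[nt - 1] * x - a[nt - 1] * y;
      Y(i, c) = y;
    }
  }
  return Y;
}
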