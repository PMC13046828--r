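#include <Rcpp.h>
using namespace Rcpp;

// Max |cluster-mass| permutation null for a paired design.
//
// D: n x P matrix of per-participant condition differences at P
// (channel, sample) points. Each permutation flips the sign of every
// participant's difference with probability 1/2 (drawn from R's RNG so
// results follow set.seed()), recomputes the paired t at every point,
// groups suprathreshold points of equal sign into clusters over the
// supplied point adjacency (CSR: nb_ptr of length P+1, nb_idx 0-based),
// and records the largest absolute summed-t cluster mass.
// [[Rcpp::export(name = ".perm_cluster_max")]]
NumericVector perm_cluster_max(NumericMatrix D, double thresh,
                               IntegerVector nb_ptr, IntegerVector nb_idx,
                               int n_perm) {
  const int n = D.nrow(), P = D.ncol();
  std::vector<double> ss(P, 0.0);
  for (int p = 0; p < P; ++p) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, p) * D(i, p);
    ss[p] = s;
  }
  NumericVector out(n_perm);
  std::vector<double> tval(P);
  std::vector<signed char> sign(n);
  std::vector<char> visited(P);
  std::vector<int> stack(P);
  RNGScope scope;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) sign[i] = unif_rand() < 0.5 ? -1 : 1;
    for (int p = 0; p < P; ++p) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += sign[i] * D(i, p);
      m /= n;
      double v = (ss[p] - n * m * m) / (n - 1);
      tval[p] = (v > 0.0) ? m / std::sqrt(v / n) : 0.0;
    }
    std::fill(visited.begin(), visited.end(), 0);
    double best = 0.0;
    for (int p = 0; p < P; ++p) {
      if (visited[p] || std::abs(tval[p]) <= thresh) continue;
      const int pol = tval[p] > 0 ? 1 : -1;
      double mass = 0.0;
      int top = 0;
      stack[top++] = p;
      visited[p] = 1;
      while (top > 0) {
        int q = stack[--top];
        mass += tval[q];
        for (int k = nb_ptr[q]; k < nb_ptr[q + 1]; ++k) {
          int r = nb_idx[k];
          if (!visited[r] && std::abs(tval[r]) > thresh &&
              ((tval[r] > 0 ? 1 : -1) == pol)) {
            visited[r] = 1;
            stack[top++] = r;
          }
        }
      }
      if (std::abs(mass) > best) best = std::abs(mass);
    }
    out[b] = best;
  }
  return out;
}
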