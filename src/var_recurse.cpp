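#include <Rcpp.h>
using namespace Rcpp;

// MVAR recursion x_t = sum_k C_k x_{t-k} + e_t with zero initial history.
// innov holds pre-generated innovations (n x (burn + nkeep)); the first
// `burn` columns are discarded from the output so transients die out.
// [[Rcpp::export]]
NumericMatrix var_recurse(List coeffs, NumericMatrix innov, int burn) {
  const int p = coeffs.size();
  const int n = innov.nrow();
  const int total = innov.ncol();
  if (burn < 0 || burn >= total)
    stop("burn-in must be shorter than the innovation sequence");
  std::vector<NumericMatrix> C(p);
  for (int k = 0; k < p; ++k) {
    C[k] = as<NumericMatrix>(coeffs[k]);
    if (C[k].nrow() != n || C[k].ncol() != n)
      stop("coefficient dimension mismatch");
  }
  NumericMatrix X(n, total);
  for (int t = 0; t < total; ++t) {
    for (int i = 0; i < n; ++i) X(i, t) = innov(i, t);
    for (int k = 0; k < p; ++k) {
      const int tl = t - k - 1;
      if (tl < 0) break;
      const NumericMatrix& A = C[k];
      for (int j = 0; j < n; ++j) {
        const double xj = X(j, tl);
        if (xj == 0.0) continue;
        for (int i = 0; i < n; ++i) X(i, t) += A(i, j) * xj;
      }
    }
  }
  NumericMatrix out(n, total - burn);
  for (int t = burn; t < total; ++t)
    for (int i = 0; i < n; ++i) out(i, t - burn) = X(i, t);
  return out;
}
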