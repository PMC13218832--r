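#include <Rcpp.h>
using namespace Rcpp;

// C = F P F' + diag(q) for sparse F (dgCMatrix) and dense symmetric P.
// Two passes over the CSC structure: B = P F' (column-contiguous
// accumulation), then C = F B. Cost 2 * nnz(F) * n.

// [[Rcpp::export]]
NumericMatrix sp_fpft(S4 F, NumericMatrix P, NumericVector q) {
  IntegerVector Fi_ = F.slot("i"), Fp_ = F.slot("p");
  NumericVector Fx_ = F.slot("x");
  IntegerVector dims = F.slot("Dim");
  const int n = dims[0];
  if (P.nrow() != n || P.ncol() != n) stop("dimension mismatch");
  if (q.size() != n) stop("q must have length n");
  const int *Fi = Fi_.begin(), *Fp = Fp_.begin();
  const double *Fx = Fx_.begin();
  const double *Pd = P.begin();

  NumericMatrix B_(n, n);  // B = P F'
  double *B = B_.begin();
  for (int j = 0; j < n; ++j) {
    const double *Pj = Pd + (size_t)j * n;
    for (int k = Fp[j]; k < Fp[j + 1]; ++k) {
      const double v = Fx[k];
      double *Bi = B + (size_t)Fi[k] * n;
      for (int r = 0; r < n; ++r) Bi[r] += v * Pj[r];
    }
  }
  NumericMatrix C_(n, n);  // C = F B + diag(q)
  double *C = C_.begin();
  for (int c = 0; c < n; ++c) {
    const double *Bc = B + (size_t)c * n;
    double *Cc = C + (size_t)c * n;
    for (int j = 0; j < n; ++j) {
      const double bj = Bc[j];
      if (bj == 0.0) continue;
      for (int k = Fp[j]; k < Fp[j + 1]; ++k) Cc[Fi[k]] += Fx[k] * bj;
    }
    Cc[c] += q[c];
  }
  return C_;
}
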