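#include <Rcpp.h>
using namespace Rcpp;

// In-place shifted accumulations used by the causal dilated convolutions.
// Both operands are package-internal scratch matrices (never user data),
// so in-place mutation is safe.

// Z[, (sh+1):L] += M[, 1:(L-sh)]
// [[Rcpp::export(name = ".shiftAddRight")]]
void shift_add_right(NumericMatrix Z, NumericMatrix M, int sh) {
  int K = Z.nrow(), L = Z.ncol();
  if (M.nrow() != K || M.ncol() != L) stop("shape mismatch");
  if (sh < 0 || sh >= L) return;
  double *z = Z.begin(), *m = M.begin();
  for (int t = sh; t < L; ++t) {
    double *zc = z + (R_xlen_t)t * K;
    double *mc = m + (R_xlen_t)(t - sh) * K;
    for (int k = 0; k < K; ++k) zc[k] += mc[k];
  }
}

// D[, 1:(L-sh)] += V[, (sh+1):L]
// [[Rcpp::export(name = ".shiftAddLeft")]]
void shift_add_left(NumericMatrix D, NumericMatrix V, int sh) {
  int K = D.nrow(), L = D.ncol();
  if (V.nrow() != K || V.ncol() != L) stop("shape mismatch");
  if (sh < 0 || sh >= L) return;
  double *d = D.begin(), *v = V.begin();
  for (int t = sh; t < L; ++t) {
    double *dc = d + (R_xlen_t)(t - sh) * K;
    double *vc = v + (R_xlen_t)t * K;
    for (int k = 0; k < K; ++k) dc[k] += vc[k];
  }
}
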