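#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ILU(0) factorization of a square sparse matrix in CSR form (0-based
// indices, column indices sorted within each row). L (unit diagonal) and U
// share the sparsity pattern of A; factors are returned in a single value
// array laid out like Ax, plus the position of each diagonal entry.
// [[Rcpp::export(name = ".ilu0_csr")]]
List ilu0_csr(int n, IntegerVector Ap, IntegerVector Aj, NumericVector Ax) {
  NumericVector Lx = clone(Ax);
  IntegerVector diag(n, -1);
  std::vector<int> pos(n, -1);  // column -> position within current row

  for (int i = 0; i < n; ++i) {
    for (int q = Ap[i]; q < Ap[i + 1]; ++q) {
      pos[Aj[q]] = q;
      if (Aj[q] == i) diag[i] = q;
    }
    for (int q = Ap[i]; q < Ap[i + 1]; ++q) {
      int k = Aj[q];
      if (k >= i) break;
      double piv = Lx[diag[k]];
      if (piv == 0.0) continue;  // skipped pivot: factor stays usable
      double lik = Lx[q] / piv;
      Lx[q] = lik;
      for (int r = diag[k] + 1; r < Ap[k + 1]; ++r) {
        int j = Aj[r];
        int p = pos[j];
        if (p >= 0) Lx[p] -= lik * Lx[r];
      }
    }
    if (diag[i] < 0) stop("ILU(0): structurally missing diagonal in row %d", i + 1);
    if (Lx[diag[i]] == 0.0) {
      // zero pivot: nudge so triangular solves stay finite
      double scale = 0.0;
      for (int q = Ap[i]; q < Ap[i + 1]; ++q) scale = std::max(scale, std::fabs(Lx[q]));
      Lx[diag[i]] = (scale > 0.0 ? scale : 1.0) * 1e-12;
    }
    for (int q = Ap[i]; q < Ap[i + 1]; ++q) pos[Aj[q]] = -1;
  }
  return List::create(_["Lx"] = Lx, _["diag"] = diag);
}

// Solve (L U) x = b with the packed ILU(0) factors from ilu0_csr.
// [[Rcpp::export(name = ".ilu0_solve")]]
NumericVector ilu0_solve(int n, IntegerVector Ap, IntegerVector Aj,
                         NumericVector Lx, IntegerVector diag, NumericVector b) {
  NumericVector x = clone(b);
  for (int i = 0; i < n; ++i) {           // forward: L (unit diagonal)
    double s = x[i];
    for (int q = Ap[i]; q < diag[i]; ++q) s -= Lx[q] * x[Aj[q]];
    x[i] = s;
  }
  for (int i = n - 1; i >= 0; --i) {      // backward: U
    double s = x[i];
    for (int q = diag[i] + 1; q < Ap[i + 1]; ++q) s -= Lx[q] * x[Aj[q]];
    x[i] = s / Lx[diag[i]];
  }
  return x;
}
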