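// In-place SGD rank-B update for large dense layers:
//   W (m x n)  <-  W - lr * dz (m x B) %*% t(A) (A is n x B)
// Folding the weight-gradient GEMM into the update (beta = 1) avoids
// materializing a gradient matrix the size of W, which dominates runtime
// for the 130k-feature dense layers. The caller owns W and must have
// duplicated it if value semantics are required.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

// [[Rcpp::export(name = ".sgd_gemm_update_cpp")]]
void sgd_gemm_update_cpp(Rcpp::NumericMatrix W, Rcpp::NumericMatrix dz,
                         Rcpp::NumericMatrix A, double lr) {
  int m = W.nrow(), n = W.ncol(), k = dz.ncol();
  if (dz.nrow() != m || A.nrow() != n || A.ncol() != k)
    Rcpp::stop("dimension mismatch in SGD update");
  double alpha = -lr, beta = 1.0;
  F77_CALL(dgemm)("N", "T", &m, &n, &k, &alpha, dz.begin(), &m,
                  A.begin(), &n, &beta, W.begin(), &m FCONE FCONE);
}
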