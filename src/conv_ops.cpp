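// Hot kernels of the 1-D convolution engine: gather (im2col) and
// scatter-add (col2im) along precomputed tap indices (0 = zero padding).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& A, const IntegerMatrix& idx) {
    const int C = A.nrow();
    const int k = idx.nrow();
    const int M = idx.ncol();
    NumericMatrix out(C * k, M);
    const double* a = REAL(A);
    double* o = REAL(out);
    const int* ix = INTEGER(idx);
    const int CK = C * k;
    for (int m = 0; m < M; ++m) {
        for (int j = 0; j < k; ++j) {
            const int src = ix[m * k + j];
            double* dst = o + (R_xlen_t)m * CK + (R_xlen_t)j * C;
            if (src > 0) {
                const double* s = a + (R_xlen_t)(src - 1) * C;
                for (int c = 0; c < C; ++c) dst[c] = s[c];
            }
        }
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dXcol,
                         const IntegerMatrix& idx, const int C) {
    const int k = idx.nrow();
    const int M = idx.ncol();
    NumericMatrix dA(C, M);
    const double* x = REAL(dXcol);
    double* o = REAL(dA);
    const int* ix = INTEGER(idx);
    const int CK = C * k;
    for (int m = 0; m < M; ++m) {
        for (int j = 0; j < k; ++j) {
            const int dst = ix[m * k + j];
            if (dst > 0) {
                double* d = o + (R_xlen_t)(dst - 1) * C;
                const double* s = x + (R_xlen_t)m * CK + (R_xlen_t)j * C;
                for (int c = 0; c < C; ++c) d[c] += s[c];
            }
        }
    }
    return dA;
}

// In-place Adam update: p, m, v are owned exclusively by the optimizer
// loop (deep-copied at checkpoint and API boundaries), so mutating them
// avoids allocating four large temporaries per tensor per step.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector p, NumericVector m, NumericVector v,
                     const NumericVector& g, const double lr,
                     const double b1, const double b2,
                     const double c1, const double c2, const double eps) {
    const R_xlen_t n = p.size();
    double* pp = REAL(p);
    double* pm = REAL(m);
    double* pv = REAL(v);
    const double* pg = REAL(g);
    for (R_xlen_t i = 0; i < n; ++i) {
        pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
        pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
        pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
    }
}
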