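// 1-D convolution kernels for the network engine.
//
// Each convolution is computed as a family of small accumulating GEMMs
// through R's BLAS: for every batch element and kernel offset k, the
// contiguous slab W[,,k] (F x C) multiplies the shifted input view
// (C x To') in place into the output. No im2col buffer is materialized,
// so the only allocations are the outputs themselves and the backward
// pass reuses the original input as its cache. Padding is handled by
// clipping the valid output range per offset. Single-threaded and
// deterministic.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static const char* NT = "N";
static const char* TT = "T";
static const double ONE = 1.0;

// X: (C, T, B); W: (F, C, K); b: length F. Y = conv(X, W) + b, (F, To, B).
// [[Rcpp::export(name = ".convForwardCpp")]]
NumericVector convForwardCpp(NumericVector X, NumericVector W,
                             NumericVector b, int padLeft, int padRight) {
    IntegerVector xd = X.attr("dim");
    const int C = xd[0], T = xd[1], B = xd[2];
    IntegerVector wd = W.attr("dim");
    const int F = wd[0], K = wd[2];
    if (wd[1] != C) stop("channel mismatch between input and kernels");
    const int To = T + padLeft + padRight - K + 1;
    if (To < 1) stop("input length too short for kernel size");

    NumericVector Yr(no_init((R_xlen_t)F * To * B));
    double* y = Yr.begin();
    const double* bp = b.begin();
    for (R_xlen_t j = 0; j < (R_xlen_t)To * B; ++j)
        for (int f = 0; f < F; ++f) y[j * F + f] = bp[f];

    const double* xp = X.begin();
    const double* wp = W.begin();
    for (int ib = 0; ib < B; ++ib) {
        const double* xb = xp + (size_t)ib * C * T;
        double* yb = y + (size_t)ib * F * To;
        for (int k = 0; k < K; ++k) {
            int t0 = padLeft - k; if (t0 < 0) t0 = 0;
            int t1 = T + padLeft - k; if (t1 > To) t1 = To;
            const int len = t1 - t0;
            if (len <= 0) continue;
            const int o0 = t0 + k - padLeft;
            F77_CALL(dgemm)(NT, NT, &F, &len, &C, &ONE,
                            wp + (size_t)k * F * C, &F,
                            xb + (size_t)o0 * C, &C, &ONE,
                            yb + (size_t)t0 * F, &F FCONE FCONE);
        }
    }
    Yr.attr("dim") = IntegerVector::create(F, To, B);
    return Yr;
}

// dY: (F, To, B); X: the forward input (C, T, B); W: (F, C, K).
// Returns dW, db, dX.
// [[Rcpp::export(name = ".convBackwardCpp")]]
List convBackwardCpp(NumericVector dY, NumericVector X, NumericVector W,
                     int padLeft) {
    IntegerVector yd = dY.attr("dim");
    const int F = yd[0], To = yd[1], B = yd[2];
    IntegerVector xd = X.attr("dim");
    const int C = xd[0], T = xd[1];
    IntegerVector wd = W.attr("dim");
    const int K = wd[2];
    if (wd[0] != F || wd[1] != C) stop("shape mismatch in conv backward");

    NumericVector dWr((R_xlen_t)F * C * K);        // zero-initialized
    NumericVector dbr(F);
    NumericVector dXr((R_xlen_t)C * T * B);
    double* dw = dWr.begin();
    double* db = dbr.begin();
    double* dx = dXr.begin();
    const double* dy = dY.begin();
    const double* xp = X.begin();
    const double* wp = W.begin();

    for (R_xlen_t j = 0; j < (R_xlen_t)To * B; ++j)
        for (int f = 0; f < F; ++f) db[f] += dy[j * F + f];

    for (int ib = 0; ib < B; ++ib) {
        const double* xb = xp + (size_t)ib * C * T;
        const double* dyb = dy + (size_t)ib * F * To;
        double* dxb = dx + (size_t)ib * C * T;
        for (int k = 0; k < K; ++k) {
            int t0 = padLeft - k; if (t0 < 0) t0 = 0;
            int t1 = T + padLeft - k; if (t1 > To) t1 = To;
            const int len = t1 - t0;
            if (len <= 0) continue;
            const int o0 = t0 + k - padLeft;
            // dW[,,k] += dY_b[, t0:t1) * X_b[, o0:o0+len)^T
            F77_CALL(dgemm)(NT, TT, &F, &C, &len, &ONE,
                            dyb + (size_t)t0 * F, &F,
                            xb + (size_t)o0 * C, &C, &ONE,
                            dw + (size_t)k * F * C, &F FCONE FCONE);
            // dX_b[, o0:o0+len) += W[,,k]^T * dY_b[, t0:t1)
            F77_CALL(dgemm)(TT, NT, &C, &len, &F, &ONE,
                            wp + (size_t)k * F * C, &F,
                            dyb + (size_t)t0 * F, &F, &ONE,
                            dxb + (size_t)o0 * C, &C FCONE FCONE);
        }
    }
    dWr.attr("dim") = IntegerVector::create(F, C, K);
    dXr.attr("dim") = IntegerVector::create(C, T, B);
    return List::create(_["dW"] = dWr, _["db"] = dbr, _["dX"] = dXr);
}
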