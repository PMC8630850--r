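// Fused elementwise layer kernels: batch normalization, ReLU, max
// pooling, inverted dropout and the Adam update. Each is a one- or
// two-pass loop over the tensor, avoiding the temporaries a vectorized
// R formulation would allocate. Dropout draws from R's RNG so seeded
// runs are reproducible. Single-threaded and deterministic.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x: (F, N) column-major. Training mode: batch statistics per row,
// running stats updated with `momentum`; returns y, xhat, istd and the
// updated running stats. Inference mode: running stats only, returns y.
// [[Rcpp::export(name = ".bnForwardCpp")]]
List bnForwardCpp(NumericMatrix x, NumericVector gamma, NumericVector beta,
                  NumericVector runMean, NumericVector runVar,
                  bool training, double momentum, double eps) {
    const int F = x.nrow();
    const R_xlen_t N = x.ncol();
    const double* xp = x.begin();
    if (!training) {
        NumericMatrix y(no_init(F, N));
        double* yp = y.begin();
        std::vector<double> a(F), c(F);
        for (int f = 0; f < F; ++f) {
            const double istd = 1.0 / std::sqrt(runVar[f] + eps);
            a[f] = gamma[f] * istd;
            c[f] = beta[f] - a[f] * runMean[f];
        }
        for (R_xlen_t j = 0; j < N; ++j)
            for (int f = 0; f < F; ++f)
                yp[j * F + f] = a[f] * xp[j * F + f] + c[f];
        return List::create(_["y"] = y);
    }
    std::vector<double> sum(F, 0.0), sumsq(F, 0.0);
    for (R_xlen_t j = 0; j < N; ++j)
        for (int f = 0; f < F; ++f) {
            const double v = xp[j * F + f];
            sum[f] += v;
            sumsq[f] += v * v;
        }
    NumericVector mu(F), var(F), istd(F), rm(F), rv(F);
    for (int f = 0; f < F; ++f) {
        mu[f] = sum[f] / N;
        var[f] = sumsq[f] / N - mu[f] * mu[f];
        if (var[f] < 0) var[f] = 0;
        istd[f] = 1.0 / std::sqrt(var[f] + eps);
        rm[f] = momentum * runMean[f] + (1 - momentum) * mu[f];
        rv[f] = momentum * runVar[f] + (1 - momentum) * var[f];
    }
    NumericMatrix y(no_init(F, N)), xhat(no_init(F, N));
    double* yp = y.begin();
    double* xh = xhat.begin();
    for (R_xlen_t j = 0; j < N; ++j)
        for (int f = 0; f < F; ++f) {
            const double h = (xp[j * F + f] - mu[f]) * istd[f];
            xh[j * F + f] = h;
            yp[j * F + f] = gamma[f] * h + beta[f];
        }
    return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                        _["runMean"] = rm, _["runVar"] = rv);
}

// [[Rcpp::export(name = ".bnBackwardCpp")]]
List bnBackwardCpp(NumericMatrix dY, NumericMatrix xhat, NumericVector istd,
                   NumericVector gamma) {
    const int F = dY.nrow();
    const R_xlen_t N = dY.ncol();
    const double* dy = dY.begin();
    const double* xh = xhat.begin();
    NumericVector dgamma(F), dbeta(F);
    for (R_xlen_t j = 0; j < N; ++j)
        for (int f = 0; f < F; ++f) {
            const double d = dy[j * F + f];
            dbeta[f] += d;
            dgamma[f] += d * xh[j * F + f];
        }
    NumericMatrix dX(no_init(F, N));
    double* dx = dX.begin();
    std::vector<double> m1(F), m2(F), s(F);
    for (int f = 0; f < F; ++f) {
        m1[f] = gamma[f] * dbeta[f] / N;      // mean of dxhat
        m2[f] = gamma[f] * dgamma[f] / N;     // mean of dxhat * xhat
        s[f] = istd[f];
    }
    for (R_xlen_t j = 0; j < N; ++j)
        for (int f = 0; f < F; ++f)
            dx[j * F + f] = s[f] * (gamma[f] * dy[j * F + f] - m1[f] -
                                    xh[j * F + f] * m2[f]);
    return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                        _["dX"] = dX);
}

// y = max(x, 0); mask returned for the backward pass.
// [[Rcpp::export(name = ".reluForwardCpp")]]
List reluForwardCpp(NumericVector x, bool wantMask) {
    const R_xlen_t n = x.size();
    NumericVector y(no_init(n));
    const double* xp = x.begin();
    double* yp = y.begin();
    if (wantMask) {
        LogicalVector mask(no_init(n));
        int* mp = mask.begin();
        for (R_xlen_t i = 0; i < n; ++i) {
            const bool pos = xp[i] > 0;
            mp[i] = pos;
            yp[i] = pos ? xp[i] : 0.0;
        }
        y.attr("dim") = x.attr("dim");
        return List::create(_["y"] = y, _["mask"] = mask);
    }
    for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
    y.attr("dim") = x.attr("dim");
    return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".maskMultiplyCpp")]]
NumericVector maskMultiplyCpp(NumericVector dY, LogicalVector mask) {
    const R_xlen_t n = dY.size();
    NumericVector out(no_init(n));
    const double* dy = dY.begin();
    const int* mp = mask.begin();
    double* op = out.begin();
    for (R_xlen_t i = 0; i < n; ++i) op[i] = mp[i] ? dy[i] : 0.0;
    out.attr("dim") = dY.attr("dim");
    return out;
}

// Max pooling over positions. X: (F, T, B); stride == size, remainder
// dropped. Returns Y (F, To, B) and the argmax offset (1-based).
// [[Rcpp::export(name = ".poolForwardCpp")]]
List poolForwardCpp(NumericVector X, int size) {
    IntegerVector xd = X.attr("dim");
    const int F = xd[0], T = xd[1], B = xd[2];
    const int To = T / size;
    if (To < 1) stop("input length too short for pool size");
    NumericVector Y(no_init((R_xlen_t)F * To * B));
    IntegerVector arg(no_init((R_xlen_t)F * To * B));
    const double* xp = X.begin();
    double* yp = Y.begin();
    int* ap = arg.begin();
    for (int ib = 0; ib < B; ++ib) {
        const double* xb = xp + (size_t)ib * F * T;
        double* yb = yp + (size_t)ib * F * To;
        int* ab = ap + (size_t)ib * F * To;
        for (int t = 0; t < To; ++t)
            for (int f = 0; f < F; ++f) {
                double best = xb[(size_t)(t * size) * F + f];
                int bj = 1;
                for (int j = 1; j < size; ++j) {
                    const double v = xb[(size_t)(t * size + j) * F + f];
                    if (v > best) { best = v; bj = j + 1; }
                }
                yb[(size_t)t * F + f] = best;
                ab[(size_t)t * F + f] = bj;
            }
    }
    Y.attr("dim") = IntegerVector::create(F, To, B);
    arg.attr("dim") = IntegerVector::create(F, To, B);
    return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".poolBackwardCpp")]]
NumericVector poolBackwardCpp(NumericVector dY, IntegerVector arg,
                              int size, int Tin) {
    IntegerVector yd = dY.attr("dim");
    const int F = yd[0], To = yd[1], B = yd[2];
    NumericVector dX((R_xlen_t)F * Tin * B);   // zero-initialized
    const double* dy = dY.begin();
    const int* ap = arg.begin();
    double* dx = dX.begin();
    for (int ib = 0; ib < B; ++ib) {
        const double* dyb = dy + (size_t)ib * F * To;
        const int* ab = ap + (size_t)ib * F * To;
        double* dxb = dx + (size_t)ib * F * Tin;
        for (int t = 0; t < To; ++t)
            for (int f = 0; f < F; ++f) {
                const int j = ab[(size_t)t * F + f] - 1;
                dxb[(size_t)(t * size + j) * F + f] += dyb[(size_t)t * F + f];
            }
    }
    dX.attr("dim") = IntegerVector::create(F, Tin, B);
    return dX;
}

// Inverted dropout using R's RNG stream (keeps seeded runs reproducible).
// Returns y = x * keep and the keep mask (0 or 1/(1-rate)).
// [[Rcpp::export(name = ".dropoutForwardCpp")]]
List dropoutForwardCpp(NumericVector x, double rate) {
    const R_xlen_t n = x.size();
    NumericVector y(no_init(n)), keep(no_init(n));
    const double scale = 1.0 / (1.0 - rate);
    const double* xp = x.begin();
    double* yp = y.begin();
    double* kp = keep.begin();
    GetRNGstate();
    for (R_xlen_t i = 0; i < n; ++i) {
        const double k = unif_rand() >= rate ? scale : 0.0;
        kp[i] = k;
        yp[i] = xp[i] * k;
    }
    PutRNGstate();
    y.attr("dim") = x.attr("dim");
    keep.attr("dim") = x.attr("dim");
    return List::create(_["y"] = y, _["keep"] = keep);
}

// One fused Adam update; returns the new parameter and moment vectors.
// [[Rcpp::export(name = ".adamUpdateCpp")]]
List adamUpdateCpp(NumericVector par, NumericVector m, NumericVector v,
                   NumericVector grad, double lr, double beta1,
                   double beta2, double eps, double corr1, double corr2) {
    const R_xlen_t n = par.size();
    NumericVector p2(no_init(n)), m2(no_init(n)), v2(no_init(n));
    const double* pp = par.begin();
    const double* mp = m.begin();
    const double* vp = v.begin();
    const double* gp = grad.begin();
    double* p2p = p2.begin();
    double* m2p = m2.begin();
    double* v2p = v2.begin();
    for (R_xlen_t i = 0; i < n; ++i) {
        const double g = gp[i];
        const double mi = beta1 * mp[i] + (1 - beta1) * g;
        const double vi = beta2 * vp[i] + (1 - beta2) * g * g;
        m2p[i] = mi;
        v2p[i] = vi;
        p2p[i] = pp[i] - lr * (mi / corr1) / (std::sqrt(vi / corr2) + eps);
    }
    p2.attr("dim") = par.attr("dim");
    return List::create(_["par"] = p2, _["m"] = m2, _["v"] = v2);
}
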