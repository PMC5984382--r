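#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One analysis step of the wavelet filter bank: symmetric extension of the
// signal by L-1 samples on each side, convolution with the analysis pair,
// downsampling by two. Output length floor((n + L - 1) / 2).
// [[Rcpp::export(name = ".dwtStepCpp")]]
List dwtStepCpp(NumericVector x, NumericVector lo, NumericVector hi) {
    const int n = x.size(), L = lo.size(), p = L - 1;
    const int ne = n + 2 * p;
    std::vector<double> ext(ne);
    for (int i = 0; i < p; ++i) ext[i] = x[p - 1 - i];
    for (int i = 0; i < n; ++i) ext[p + i] = x[i];
    for (int i = 0; i < p; ++i) ext[p + n + i] = x[n - 1 - i];
    const int out_len = (n + L - 1) / 2;
    NumericVector cA(out_len), cD(out_len);
    const double *pe = ext.data(), *plo = REAL(lo), *phi = REAL(hi);
    double *pa = REAL(cA), *pd = REAL(cD);
    for (int i = 0; i < out_len; ++i) {
        const double *v = pe + L + 2 * i;    // ext index for filter tap 0
        double a = 0.0, d = 0.0;
        for (int k = 0; k < L; ++k) {
            a += plo[k] * v[-k];
            d += phi[k] * v[-k];
        }
        pa[i] = a;
        pd[i] = d;
    }
    return List::create(_["cA"] = cA, _["cD"] = cD);
}

// One synthesis step: upsample both coefficient sequences, convolve with
// the synthesis pair, sum, and trim to the length of the signal that was
// decomposed at this level.
// [[Rcpp::export(name = ".idwtStepCpp")]]
NumericVector idwtStepCpp(NumericVector cA, NumericVector cD,
                          NumericVector lo, NumericVector hi,
                          int origLen) {
    const int m = cA.size(), L = lo.size();
    NumericVector out(origLen);
    const double *pa = REAL(cA), *pd = REAL(cD);
    const double *plo = REAL(lo), *phi = REAL(hi);
    double *po = REAL(out);
    // out[i] = sum_k lo[k] * upA[L - 2 + i - k] + hi[k] * upD[...] where
    // up* holds the coefficients at even 0-based positions (2j).
    for (int i = 0; i < origLen; ++i) {
        double s = 0.0;
        for (int k = 0; k < L; ++k) {
            const int q = L - 2 + i - k;     // index into the upsampled seq
            if (q < 0 || q >= 2 * m || (q & 1)) continue;
            const int j = q >> 1;
            s += plo[k] * pa[j] + phi[k] * pd[j];
        }
        po[i] = s;
    }
    return out;
}
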