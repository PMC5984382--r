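#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static double entropyFromCounts(const std::vector<double>& cnt, double n) {
    if (n <= 0) return 0.0;
    double h = 0.0;
    for (double c : cnt) {
        if (c > 0) {
            double p = c / n;
            h -= p * std::log2(p);
        }
    }
    return h;
}

// Exhaustive gain-ratio split search over all (feature, midpoint-threshold)
// candidates. Ties resolve to the lower feature index, then the lower
// threshold. A split qualifies only if both children hold >= minLeaf
// samples and its information gain is positive.
//
// Returns list(feature, threshold, gain_ratio, gain); feature == -1 when no
// admissible split exists.
// [[Rcpp::export(name = ".bestSplitCpp")]]
List bestSplitCpp(NumericMatrix X, IntegerVector y, int nClasses,
                  int minLeaf) {
    const int n = X.nrow(), p = X.ncol();
    int bestFeature = -1;
    double bestThreshold = NA_REAL, bestGR = -1.0, bestGain = 0.0;
    const double eps = 1e-12;

    std::vector<double> total(nClasses, 0.0);
    for (int i = 0; i < n; ++i) total[y[i]] += 1.0;
    const double hRoot = entropyFromCounts(total, n);

    std::vector<int> ord(n);
    std::vector<double> left(nClasses);

    for (int j = 0; j < p; ++j) {
        NumericMatrix::Column col = X(_, j);
        for (int i = 0; i < n; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
            return col[a] < col[b];
        });
        std::fill(left.begin(), left.end(), 0.0);
        for (int k = 0; k < n - 1; ++k) {
            left[y[ord[k]]] += 1.0;
            double v = col[ord[k]], vNext = col[ord[k + 1]];
            if (vNext <= v) continue;            // not a class boundary in value
            int nl = k + 1, nr = n - nl;
            if (nl < minLeaf || nr < minLeaf) continue;
            double hl = entropyFromCounts(left, nl);
            double hr;
            {
                std::vector<double> right(nClasses);
                for (int c = 0; c < nClasses; ++c)
                    right[c] = total[c] - left[c];
                hr = entropyFromCounts(right, nr);
            }
            double pl = (double)nl / n, pr = (double)nr / n;
            double gain = hRoot - (pl * hl + pr * hr);
            if (gain <= eps) continue;
            double splitInfo = -(pl * std::log2(pl) + pr * std::log2(pr));
            if (splitInfo < eps) continue;
            double gr = gain / splitInfo;
            if (gr > bestGR + eps) {
                bestGR = gr;
                bestGain = gain;
                bestFeature = j + 1;
                bestThreshold = (v + vNext) / 2.0;
            }
        }
    }
    return List::create(_["feature"] = bestFeature,
                        _["threshold"] = bestThreshold,
                        _["gain_ratio"] = bestGR,
                        _["gain"] = bestGain);
}
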