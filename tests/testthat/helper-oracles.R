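# Independent oracles used across the suite. These deliberately use naive
# direct computations (O(n^2) sums, exhaustive enumeration, base-R
# periodograms) so they share no code with the implementation they check.

# Direct O(S^2) evaluation of the DFT sum.
naiveDFT <- function(x) {
    S <- length(x)
    vapply(0:(S - 1), function(k)
        sum(x * exp(-2i * pi * k * (0:(S - 1)) / S)), complex(1))
}

# Mean band power of one channel from a raw periodogram.
periodogramBandPower <- function(x, fs, f_lo, f_hi) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0, detrend = FALSE)
    sel <- sp$freq > f_lo & sp$freq <= f_hi
    mean(sp$spec[sel])
}

# Dominant frequency of one channel from a raw periodogram.
periodogramPeak <- function(x, fs) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0, detrend = FALSE)
    sp$freq[which.max(sp$spec)]
}

entropyOracle <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
}

# Exhaustive enumeration of every (feature, midpoint threshold) candidate,
# mirroring the C4.5 admissibility rules: both children >= minLeaf and
# positive information gain. Ties resolve to the lower feature index, then
# the lower threshold.
bruteBestSplit <- function(X, y, minLeaf = 2) {
    n <- nrow(X)
    hRoot <- entropyOracle(table(y))
    best <- list(feature = -1L, threshold = NA_real_, gain_ratio = -1,
                 gain = 0)
    for (j in seq_len(ncol(X))) {
        v <- sort(unique(X[, j]))
        if (length(v) < 2) next
        for (thr in (v[-length(v)] + v[-1]) / 2) {
            left <- X[, j] <= thr
            nl <- sum(left); nr <- n - nl
            if (nl < minLeaf || nr < minLeaf) next
            gain <- hRoot - (nl / n * entropyOracle(table(y[left])) +
                             nr / n * entropyOracle(table(y[!left])))
            if (gain <= 1e-12) next
            si <- -(nl / n * log2(nl / n) + nr / n * log2(nr / n))
            gr <- gain / si
            if (gr > best$gain_ratio + 1e-12)
                best <- list(feature = j, threshold = thr,
                             gain_ratio = gr, gain = gain)
        }
    }
    best
}

# Direct conditional-entropy computation of the information gain of one
# feature after equal-width binning.
bruteInfoGain <- function(x, y, n_bins = 10) {
    rng <- range(x)
    if (diff(rng) <= 0) return(0)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(x, edges, rightmost.closed = TRUE)
    tab <- table(bin, y)
    pb <- rowSums(tab) / sum(tab)
    entropyOracle(table(y)) -
        sum(pb * apply(tab, 1, entropyOracle))
}

# A random FeatureMatrix fixture.
randomFeatureMatrix <- function(n, p, classes = c("HC", "AD"), seed = 1) {
    set.seed(seed)
    values <- matrix(rnorm(n * p), n, p,
                     dimnames = list(paste0("s", seq_len(n)),
                                     paste0("f", seq_len(p))))
    FeatureMatrixFromValues(values, sample(classes, n, replace = TRUE))
}

# A two-class FeatureMatrix whose single informative feature separates the
# classes by `gap` standard deviations.
separableFeatureMatrix <- function(n_per_class = 10, p_noise = 0,
                                   gap = 6, seed = 1) {
    set.seed(seed)
    n <- 2 * n_per_class
    informative <- c(rnorm(n_per_class), rnorm(n_per_class) + gap)
    values <- cbind(informative,
                    if (p_noise > 0) matrix(rnorm(n * p_noise), n, p_noise))
    colnames(values) <- c("inf", if (p_noise > 0) paste0("n", seq_len(p_noise)))
    rownames(values) <- paste0("s", seq_len(n))
    FeatureMatrixFromValues(values, rep(c("HC", "AD"), each = n_per_class))
}

# A short multichannel sine recording for io tests.
sineRecording <- function(fs = 256, dur = 2, freqs = NULL,
                          channels = montageChannels()) {
    t <- (seq_len(fs * dur) - 1) / fs
    if (is.null(freqs)) freqs <- seq(2, 40, length.out = length(channels))
    mat <- vapply(seq_along(channels),
                  function(i) sin(2 * pi * freqs[i] * t),
                  numeric(length(t)))
    colnames(mat) <- channels
    Recording(mat, fs)
}
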