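#' Discrete Fourier transform of a real signal
#'
#' Computes `X[k] = sum_{s=0}^{S-1} x[s] * exp(-i 2 pi k s / S)` for
#' `k = 0 .. S-1` via the FFT. The result is contractually equal (to
#' numerical tolerance) to the direct double sum.
#'
#' @param x real-valued signal.
#' @param fs sampling rate in Hz (metadata only).
#' @return A list of class `Spectrum` with elements `values` (complex,
#'   length `S`), `fs` and `S`.
#' @examples
#' sp <- computeDFT(cos(2 * pi * 3 * (0:31) / 32))
#' round(Mod(sp$values)[1:5], 9)
#' @export
computeDFT <- function(x, fs = NA_real_) {
    if (length(x) < 1) stop("empty input")
    if (anyNA(x)) stop("input must not contain NA")
    structure(list(values = stats::fft(as.numeric(x)), fs = fs,
                   S = length(x)),
              class = "Spectrum")
}

# Split a channel into n_epochs equal non-overlapping epochs; a trailing
# remainder is dropped with a warning.
.splitEpochs <- function(x, n_epochs) {
    n <- length(x)
    len <- n %/% n_epochs
    if (len < 1) stop("signal too short for ", n_epochs, " epochs")
    if (n %% n_epochs != 0)
        warning(sprintf("dropping %d trailing samples not filling an epoch",
                        n %% n_epochs))
    lapply(seq_len(n_epochs), function(e) x[((e - 1) * len + 1):(e * len)])
}

#' Fourier band-magnitude features of a recording
#'
#' For every electrode the channel is split into `n_epochs` non-overlapping
#' epochs (default 4, i.e. 45 s epochs of a 180 s preprocessed recording).
#' Per epoch, the magnitude spectrum is averaged within `m` equal-width
#' frequency bins spanning `(0, f_max]` Hz (DC excluded), and the bins are
#' then averaged across epochs, giving `m` Fourier coefficients per
#' electrode. Electrode blocks are concatenated in canonical montage order,
#' coefficients ascending in frequency, so a 19-channel recording yields
#' `19 * m` features (304 at the default `m = 16`).
#'
#' @param rec a preprocessed [Recording-class] (nominally 256 Hz, 180 s).
#' @param m number of frequency bins per electrode (default 16).
#' @param f_max upper edge of the analyzed band in Hz (default 32, so the
#'   default bins are 2 Hz wide and cover delta through low gamma).
#' @param n_epochs number of epochs (default 4).
#' @return Named numeric vector of `n_channels * m` features, names
#'   `<electrode>_c<bin>`.
#' @export
extractFourierFeatures <- function(rec, m = 16, f_max = 32, n_epochs = 4) {
    stopifnot(is(rec, "Recording"), m >= 1, n_epochs >= 1)
    fs <- samplingRate(rec)
    if (f_max > fs / 2)
        stop(sprintf("f_max = %g Hz exceeds the Nyquist frequency %g Hz",
                     f_max, fs / 2))
    edges <- seq(0, f_max, length.out = m + 1)
    feats <- lapply(channelLabels(rec), function(ch) {
        epochs <- .splitEpochs(signalMatrix(rec)[, ch], n_epochs)
        per_epoch <- vapply(epochs, function(x) {
            S <- length(x)
            mag <- Mod(stats::fft(x)) * 2 / S
            f <- (seq_len(S) - 1) * fs / S
            keep <- f > 0 & f <= f_max
            bin <- findInterval(f[keep], edges, left.open = TRUE,
                                rightmost.closed = TRUE)
            vapply(seq_len(m), function(b) mean(mag[keep][bin == b]),
                   numeric(1))
        }, numeric(m))
        rowMeans(per_epoch)
    })
    names(feats) <- channelLabels(rec)
    out <- unlist(feats)
    names(out) <- as.vector(vapply(channelLabels(rec), function(ch)
        sprintf("%s_c%02d", ch, seq_len(m)), character(m)))
    out
}

#' Assemble feature vectors into a FeatureMatrix
#'
#' Stacks per-sample feature vectors into the serializable feature table:
#' one row per sample, one column per feature, plus the class label.
#'
#' @param vectors list of equal-length named numeric vectors.
#' @param labels class label per sample.
#' @param sample_ids optional sample identifiers (default `sample_1` ...).
#' @return A [FeatureMatrix-class].
#' @export
assembleFeatureMatrix <- function(vectors, labels, sample_ids = NULL) {
    if (length(vectors) == 0) stop("no feature vectors supplied")
    if (length(vectors) != length(labels))
        stop("labels and feature vectors are not aligned")
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1)
        stop("ragged feature vectors: lengths ",
             paste(unique(lens), collapse = ", "))
    if (is.null(sample_ids))
        sample_ids <- paste0("sample_", seq_along(vectors))
    values <- do.call(rbind, vectors)
    rownames(values) <- sample_ids
    if (is.null(colnames(values)))
        colnames(values) <- paste0("f", seq_len(ncol(values)))
    FeatureMatrixFromValues(values, labels)
}

#' @rdname FeatureMatrix-class
#' @param values samples-by-features numeric matrix with row and column names.
#' @param labels class label per sample.
#' @export
FeatureMatrixFromValues <- function(values, labels) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = t(values)),
        colData = S4Vectors::DataFrame(label = as.character(labels),
                                       row.names = rownames(values)))
    new("FeatureMatrix", se)
}

#' Write a FeatureMatrix as CSV
#'
#' One row per sample: `sample_id`, the feature columns, and a final
#' `sample_type` column with the class label.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
    df <- data.frame(sample_id = colnames(fm),
                     featureValues(fm),
                     sample_type = sampleLabels(fm),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read a FeatureMatrix from CSV
#'
#' @param path CSV file written by [writeFeatureMatrix()].
#' @return A [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!all(c("sample_id", "sample_type") %in% colnames(df)))
        stop("not a feature table: missing sample_id/sample_type columns")
    feat <- df[, setdiff(colnames(df), c("sample_id", "sample_type")),
               drop = FALSE]
    values <- as.matrix(feat)
    rownames(values) <- df$sample_id
    FeatureMatrixFromValues(values, df$sample_type)
}

#' Subset a FeatureMatrix by samples or features
#'
#' @param fm a [FeatureMatrix-class].
#' @param samples logical/integer index over samples (optional).
#' @param features character/integer index over features (optional).
#' @return A [FeatureMatrix-class].
#' @export
subsetFeatureMatrix <- function(fm, samples = NULL, features = NULL) {
    v <- featureValues(fm)
    l <- sampleLabels(fm)
    if (!is.null(samples)) {
        v <- v[samples, , drop = FALSE]
        l <- l[samples]
    }
    if (!is.null(features)) v <- v[, features, drop = FALSE]
    FeatureMatrixFromValues(v, l)
}
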