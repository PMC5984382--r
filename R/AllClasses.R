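#' @import methods
#' @importFrom stats fft rnorm runif rpois qnorm sd
NULL

#' Multichannel EEG recording
#'
#' An S4 container for one multichannel EEG recording: a samples-by-channels
#' numeric matrix of scalp potentials (microvolts) together with the sampling
#' rate. Column names are the 10-20 electrode labels in canonical montage
#' order (see [montageChannels()]).
#'
#' @slot signal numeric matrix, one column per channel, one row per sample.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [readRecording()], [trimCentral()], [resampleTo()]
#' @export
setClass("Recording",
    representation(signal = "matrix", fs = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
            msg <- c(msg, "fs must be a single positive number")
        if (!is.numeric(object@signal))
            msg <- c(msg, "signal must be a numeric matrix")
        if (anyNA(object@signal) || any(!is.finite(object@signal)))
            msg <- c(msg, "signal must not contain missing or non-finite values")
        if (is.null(colnames(object@signal)))
            msg <- c(msg, "signal must have channel labels as column names")
        else if (anyDuplicated(colnames(object@signal)))
            msg <- c(msg, "channel labels must be unique")
        if (is.null(msg)) TRUE else msg
    })

#' Construct a Recording
#'
#' @param signal numeric matrix (samples x channels) or a data.frame; column
#'   names are channel labels.
#' @param fs sampling rate in Hz.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(512), ncol = 2,
#'                         dimnames = list(NULL, c("Fp1", "Fp2"))), fs = 256)
#' nSamples(rec)
#' @export
Recording <- function(signal, fs) {
    if (is.data.frame(signal)) signal <- as.matrix(signal)
    storage.mode(signal) <- "double"
    new("Recording", signal = signal, fs = as.numeric(fs))
}

#' Sub-band decomposition of a signal
#'
#' Holds the coefficient pyramid of a discrete wavelet transform: detail
#' coefficient sequences D1..Dlevel and the approximation A_level, together
#' with the bookkeeping needed for exact reconstruction (per-level input
#' lengths) and the dyadic frequency interval of every sub-band.
#'
#' @slot wavelet wavelet family, `"sym3"` or `"db4"`.
#' @slot level decomposition depth.
#' @slot detail list of detail coefficient vectors, `detail[[i]]` is Di.
#' @slot approx approximation coefficients at the deepest level.
#' @slot fs sampling rate of the decomposed signal in Hz.
#' @slot lengths integer vector of input lengths at each level (element i is
#'   the length of the signal that was decomposed at level i), used to trim
#'   the inverse transform.
#'
#' @seealso [dwtDecompose()], [dwtReconstruct()], [bandMap()]
#' @export
setClass("SubBandDecomposition",
    representation(wavelet = "character", level = "integer",
                   detail = "list", approx = "numeric",
                   fs = "numeric", lengths = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@detail) != object@level)
            msg <- c(msg, "number of detail sequences must equal the level")
        if (length(object@lengths) != object@level)
            msg <- c(msg, "one original length per level is required")
        if (!object@wavelet %in% names(.wavelet_filters))
            msg <- c(msg, sprintf("unknown wavelet '%s'", object@wavelet))
        if (is.null(msg)) TRUE else msg
    })

#' Adaptive attenuation thresholds for one sub-band
#'
#' The pair of thresholds used by the artifact-attenuation rule: upper
#' threshold mean(x) + 1.5 sd(x) and lower threshold mean(x) - 1.5 sd(x),
#' so that `up - dwn = 3 sd(x)` by construction.
#'
#' @slot up upper threshold (same units as the sub-band, microvolts).
#' @slot dwn lower threshold.
#' @seealso [computeThresholds()], [attenuateOutliers()]
#' @export
setClass("ThresholdPair",
    representation(up = "numeric", dwn = "numeric"),
    validity = function(object) {
        if (length(object@up) != 1L || length(object@dwn) != 1L)
            return("thresholds must be scalars")
        if (object@up < object@dwn) return("up must be >= dwn")
        TRUE
    })

#' Feature matrix with class labels
#'
#' A samples-by-features matrix plus one class label per sample, stored as a
#' [SummarizedExperiment::SummarizedExperiment] (features as rows, samples as
#' columns, labels in `colData`). Serialized as a CSV table with one row per
#' sample: `sample_id, <feature columns...>, sample_type`.
#'
#' @seealso [assembleFeatureMatrix()], [writeFeatureMatrix()],
#'   [readFeatureMatrix()]
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment",
    validity = function(object) {
        msg <- NULL
        if (!"features" %in% SummarizedExperiment::assayNames(object))
            msg <- c(msg, "assay 'features' is required")
        if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
            msg <- c(msg, "colData column 'label' is required")
        else if (anyNA(SummarizedExperiment::colData(object)$label))
            msg <- c(msg, "labels must not be missing")
        if (anyNA(SummarizedExperiment::assay(object, "features")))
            msg <- c(msg, "feature values must not contain NA")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "feature names must be unique")
        if (is.null(msg)) TRUE else msg
    })

#' C4.5-style decision tree
#'
#' A binary decision tree over numeric features. Internal nodes carry a
#' (feature, threshold) test with the `<=` branch on the left; leaves carry a
#' class label, the number of training instances routed to the leaf and how
#' many of those were misclassified.
#'
#' @slot root recursive node list (internal representation).
#' @slot classes class labels the tree can predict.
#' @slot featureNames names of the features available at training time.
#' @slot nTrain number of training samples.
#' @seealso [trainC45()], [exportRules()], [predict,DecisionTree-method]
#' @export
setClass("DecisionTree",
    representation(root = "list", classes = "character",
                   featureNames = "character", nTrain = "integer"),
    validity = function(object) {
        if (length(object@classes) < 1L) return("at least one class required")
        TRUE
    })

#' Cross-validation evaluation report
#'
#' Pooled confusion matrix and summary metrics for one binary classification
#' problem under one sampling scheme. Metrics are percentages; precision,
#' sensitivity, specificity and F-measure are reported both per class and as
#' support-weighted averages across the two classes.
#'
#' @slot problem problem name, e.g. `"HCvsAD"`.
#' @slot scheme sampling scheme: `"loocv"`, `"kfold10"` or `"holdout90"`.
#' @slot nFolds number of folds actually run.
#' @slot confusion 2x2 contingency table, rows = actual, columns = predicted.
#' @slot metrics named list: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f_measure` (weighted, in percent) and `per_class`
#'   (data.frame of per-class values).
#' @seealso [crossValidate()], [metricsFromConfusion()]
#' @export
setClass("EvaluationReport",
    representation(problem = "character", scheme = "character",
                   nFolds = "integer", confusion = "matrix",
                   metrics = "list"),
    validity = function(object) {
        msg <- NULL
        if (!all(dim(object@confusion) == c(2L, 2L)))
            msg <- c(msg, "confusion must be a 2x2 matrix")
        m <- unlist(object@metrics[c("accuracy", "precision", "sensitivity",
                                     "specificity", "f_measure")])
        if (any(m < 0 | m > 100))
            msg <- c(msg, "metrics must lie in [0, 100]")
        if (is.null(msg)) TRUE else msg
    })
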