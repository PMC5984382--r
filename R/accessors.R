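#' @rdname Recording-class
#' @export
setMethod("channelLabels", "Recording", function(x) colnames(x@signal))

#' @rdname Recording-class
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @rdname Recording-class
#' @export
setMethod("nSamples", "Recording", function(x) nrow(x@signal))

#' @rdname Recording-class
#' @export
setMethod("signalMatrix", "Recording", function(x) x@signal)

#' @rdname Recording-class
#' @export
setMethod("recordingDuration", "Recording",
          function(x) nrow(x@signal) / x@fs)

setMethod("show", "Recording", function(object) {
    cat(sprintf("Recording: %d channels x %d samples (%.1f s at %g Hz)\n",
                ncol(object@signal), nrow(object@signal),
                recordingDuration(object), object@fs))
    cat("channels:", paste(channelLabels(object), collapse = " "), "\n")
})

#' @rdname SubBandDecomposition-class
#' @export
setMethod("bandMap", "SubBandDecomposition", function(x) {
    nyq <- x@fs / 2
    bands <- lapply(seq_len(x@level),
                    function(i) c(nyq / 2^i, nyq / 2^(i - 1)))
    names(bands) <- paste0("D", seq_len(x@level))
    bands[[paste0("A", x@level)]] <- c(0, nyq / 2^x@level)
    bands
})

setMethod("show", "SubBandDecomposition", function(object) {
    cat(sprintf("SubBandDecomposition: %s, level %d, fs %g Hz\n",
                object@wavelet, object@level, object@fs))
    bm <- bandMap(object)
    for (nm in names(bm))
        cat(sprintf("  %-3s [%6.3f, %7.3f) Hz, %d coefficients\n", nm,
                    bm[[nm]][1], bm[[nm]][2],
                    if (startsWith(nm, "A")) length(object@approx)
                    else length(object@detail[[as.integer(sub("D", "", nm))]])))
})

#' @rdname ThresholdPair-class
#' @export
setMethod("thrUp", "ThresholdPair", function(x) x@up)

#' @rdname ThresholdPair-class
#' @export
setMethod("thrDwn", "ThresholdPair", function(x) x@dwn)

setMethod("show", "ThresholdPair", function(object) {
    cat(sprintf("ThresholdPair: up = %g, dwn = %g\n", object@up, object@dwn))
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x)
    t(SummarizedExperiment::assay(x, "features")))

#' @rdname FeatureMatrix-class
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x)
    as.character(SummarizedExperiment::colData(x)$label))

setMethod("show", "FeatureMatrix", function(object) {
    lab <- sampleLabels(object)
    cat(sprintf("FeatureMatrix: %d samples x %d features\n",
                ncol(object), nrow(object)))
    print(table(lab))
})

#' @rdname DecisionTree-class
#' @export
setMethod("treeSize", "DecisionTree", function(x) .countNodes(x@root))

#' @rdname DecisionTree-class
#' @export
setMethod("nLeaves", "DecisionTree", function(x) .countLeaves(x@root))

.countNodes <- function(node) {
    if (node$leaf) 1L
    else 1L + .countNodes(node$left) + .countNodes(node$right)
}

.countLeaves <- function(node) {
    if (node$leaf) 1L
    else .countLeaves(node$left) + .countLeaves(node$right)
}

setMethod("show", "DecisionTree", function(object) {
    cat(sprintf("DecisionTree (C4.5): size %d, %d leaves, %d training samples\n",
                treeSize(object), nLeaves(object), object@nTrain))
    cat(exportRules(object), sep = "\n")
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: %s, %s (%d folds)\n",
                object@problem, object@scheme, object@nFolds))
    cat("confusion (rows = actual):\n")
    print(object@confusion)
    m <- object@metrics
    cat(sprintf(paste0("accuracy %.1f  precision %.1f  sensitivity %.1f  ",
                       "specificity %.1f  F-measure %.1f\n"),
                m$accuracy, m$precision, m$sensitivity,
                m$specificity, m$f_measure))
})
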