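#' @rdname Recording-class
#' @param object,x a `Recording`
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname Recording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname Recording-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname Recording-class
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname SubBandDecomposition-class
#' @param x a `SubBandDecomposition`
#' @export
setGeneric("bandMap", function(x) standardGeneric("bandMap"))

#' @rdname FeatureMatrix-class
#' @param x a `FeatureMatrix`
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname ThresholdPair-class
#' @param x a `ThresholdPair`
#' @export
setGeneric("thrUp", function(x) standardGeneric("thrUp"))

#' @rdname ThresholdPair-class
#' @export
setGeneric("thrDwn", function(x) standardGeneric("thrDwn"))

#' @rdname DecisionTree-class
#' @param x a `DecisionTree`
#' @export
setGeneric("treeSize", function(x) standardGeneric("treeSize"))

#' @rdname DecisionTree-class
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))
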