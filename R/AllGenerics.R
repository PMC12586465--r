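#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))

#' @rdname accessors
#' @export
setGeneric("measureName", function(x) standardGeneric("measureName"))

#' @rdname accessors
#' @export
setGeneric("connectivityWeights", function(x) standardGeneric("connectivityWeights"))

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' Mean connectivity over all channel pairs
#'
#' @param x a [ConnectivityMatrix-class] (or plain symmetric matrix).
#' @return mean of the upper-triangle off-diagonal entries.
#' @export
setGeneric("wholeBrainMean", function(x) standardGeneric("wholeBrainMean"))

#' Extract the maximum spanning tree
#'
#' @param x a [ConnectivityMatrix-class] or a plain symmetric non-negative
#'   weight matrix with channel dimnames.
#' @param ... passed to methods.
#' @return a [SpanningTree-class].
#' @export
setGeneric("maxSpanningTree", function(x, ...) standardGeneric("maxSpanningTree"))
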