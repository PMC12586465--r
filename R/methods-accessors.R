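#' Accessors for the core classes
#'
#' Small read-only accessors; user code should use these rather than reaching
#' into slots.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "EpochedRecording", function(x) x@fs)

#' @rdname accessors
setMethod("channelLabels", "EpochedRecording", function(x) x@channelLabels)

#' @rdname accessors
setMethod("nEpochs", "EpochedRecording", function(x) dim(x@data)[3L])

#' @rdname accessors
setMethod("nEpochs", "ConnectivityMatrix", function(x) x@nEpochs)

#' @rdname accessors
setMethod("nChannels", "EpochedRecording", function(x) dim(x@data)[1L])

#' @rdname accessors
setMethod("nChannels", "ConnectivityMatrix", function(x) nrow(x@weights))

#' @rdname accessors
setMethod("epochLength", "EpochedRecording", function(x) dim(x@data)[2L])

#' @rdname accessors
setMethod("bandOf", "EpochedRecording", function(x) x@band)

#' @rdname accessors
setMethod("bandOf", "ConnectivityMatrix", function(x) x@band)

#' @rdname accessors
setMethod("bandOf", "SpanningTree", function(x) x@band)

#' @rdname accessors
setMethod("measureName", "ConnectivityMatrix", function(x) x@measure)

#' @rdname accessors
setMethod("measureName", "SpanningTree", function(x) x@measure)

#' @rdname accessors
setMethod("connectivityWeights", "ConnectivityMatrix", function(x) x@weights)

#' @rdname accessors
setMethod("channelLabels", "ConnectivityMatrix", function(x) rownames(x@weights))

#' @rdname accessors
setMethod("treeEdges", "SpanningTree", function(x) x@edges)

#' @rdname accessors
setMethod("treeNodes", "SpanningTree", function(x) x@nodes)

setMethod("show", "BandDefinition", function(object) {
  cat(sprintf("BandDefinition '%s': %g-%g Hz\n",
              object@name, object@low, object@high))
})

setMethod("show", "EpochedRecording", function(object) {
  d <- dim(object@data)
  bd <- if (is.null(object@band)) "broadband"
        else sprintf("%s (%g-%g Hz)", object@band@name, object@band@low,
                     object@band@high)
  cat(sprintf(
    "EpochedRecording: %d channels x %d samples x %d epochs @ %g Hz\n",
    d[1L], d[2L], d[3L], object@fs))
  cat(sprintf("  band: %s | subject: %s | condition: %s\n",
              bd, object@subjectId, object@condition))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  bd <- if (is.null(object@band)) "broadband" else object@band@name
  cat(sprintf(
    "ConnectivityMatrix (%s, %s): %d channels, averaged over %d epochs\n",
    object@measure, bd, nrow(object@weights), object@nEpochs))
  ut <- object@weights[upper.tri(object@weights)]
  cat(sprintf("  weights: mean %.4f, range [%.4f, %.4f]\n",
              mean(ut, na.rm = TRUE), min(ut, na.rm = TRUE),
              max(ut, na.rm = TRUE)))
})

setMethod("show", "SpanningTree", function(object) {
  bd <- if (is.null(object@band)) "broadband" else object@band@name
  cat(sprintf("SpanningTree (%s, %s): %d nodes, %d edges, total weight %.4f\n",
              object@measure, bd, length(object@nodes), nrow(object@edges),
              sum(object@edges$weight)))
  if (object@nTies > 0L)
    cat(sprintf("  note: %d weight ties during extraction\n", object@nTies))
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  cat(sprintf("  measure table: %d rows (%d subjects, %d measure/band cells)\n",
              nrow(object@measureTable),
              length(unique(object@measureTable$subject)),
              nrow(unique(object@measureTable[, c("measure", "band")]))))
  cat(sprintf("  reliability: %d rows | overlap: %d rows\n",
              nrow(object@reliability), nrow(object@overlap)))
  cat(sprintf("  seed: %s\n", object@manifest$seed))
})
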