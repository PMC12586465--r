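#' @import methods
NULL

#' Frequency band definition
#'
#' A named frequency band with lower and upper passband edges in Hz. The
#' canonical sensor-EEG set used throughout the package is delta (0.5--4 Hz),
#' theta (4--8 Hz), alpha (8--13 Hz) and beta (13--20 Hz); content above
#' 20 Hz is excluded to limit muscle-artifact contamination.
#'
#' @slot name band label, e.g. \code{"alpha"}.
#' @slot low lower passband edge in Hz; must satisfy \code{0 < low < high}.
#' @slot high upper passband edge in Hz.
#'
#' @seealso [bandDefinition()], [canonicalBands()]
#' @export
setClass("BandDefinition",
  representation(name = "character", low = "numeric", high = "numeric"))

setValidity("BandDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@low) != 1L || length(object@high) != 1L)
    return("'low' and 'high' must be single numbers")
  if (!is.finite(object@low) || !is.finite(object@high))
    return("band edges must be finite")
  if (object@low <= 0) return("'low' must be > 0")
  if (object@low >= object@high) return("degenerate band: low >= high")
  TRUE
})

setClassUnion("BandOrNULL", c("BandDefinition", "NULL"))

#' Band-filtered multichannel recording cut into fixed-length epochs
#'
#' The unit that every estimator consumes: a multichannel signal segmented
#' into equal-length artifact-free epochs. The default study layout is 15
#' epochs of 4 s sampled at 2048 Hz on 64 channels, and three conditions per
#' subject (\code{session1}, \code{session2}, \code{semirest}).
#'
#' @slot data numeric array \code{channels x samples x epochs}.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of channel names (length = channels).
#' @slot band a [BandDefinition-class] if band-filtered, or \code{NULL} for
#'   broadband data.
#' @slot subjectId subject label.
#' @slot condition recording condition label.
#'
#' @seealso [segmentEpochs()], [bandpass()], [analyticSignal()]
#' @export
setClass("EpochedRecording",
  representation(data = "array", fs = "numeric", channelLabels = "character",
                 band = "BandOrNULL", subjectId = "character",
                 condition = "character"))

setValidity("EpochedRecording", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("'data' must be a channels x samples x epochs array")
  if (!all(is.finite(d))) return("non-finite samples in 'data'")
  if (length(object@channelLabels) != dim(d)[1L])
    return("channelLabels length must equal the number of channels")
  if (anyDuplicated(object@channelLabels))
    return("channel labels must be unique")
  if (length(object@fs) != 1L || object@fs <= 0)
    return("'fs' must be a single positive number")
  if (!is.null(object@band) && object@band@high >= object@fs / 2)
    return("band upper edge must be below the Nyquist frequency")
  TRUE
})

#' Symmetric channel-by-channel connectivity matrix
#'
#' Epoch-averaged pairwise connectivity for one measure, band and recording.
#' Weights are symmetric with zero diagonal and lie in [0, 1] for all three
#' matrix-valued measures (PLI, normalized AECc, inverted JPE).
#'
#' @slot weights symmetric numeric N x N matrix, zero diagonal.
#' @slot measure one of \code{"PLI"}, \code{"AECc"}, \code{"JPE_INV"}.
#' @slot band the [BandDefinition-class] the recording was filtered in (or
#'   \code{NULL}).
#' @slot nEpochs number of epochs averaged.
#' @slot aux list of per-measure extras (e.g. the raw signed correlation
#'   matrix for AECc, and per-pair counts of epochs dropped for degenerate
#'   envelopes).
#'
#' @seealso [connectivityMatrix()], [wholeBrainMean()], [maxSpanningTree()]
#' @export
setClass("ConnectivityMatrix",
  representation(weights = "matrix", measure = "character",
                 band = "BandOrNULL", nEpochs = "integer", aux = "list"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("'weights' must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    return("'weights' must carry identical row and column channel names")
  if (any(diag(w) != 0, na.rm = TRUE)) return("diagonal must be zero")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10,
                        check.attributes = FALSE)))
    return("'weights' must be symmetric")
  ok <- w[upper.tri(w)]
  if (any(ok < -1e-10 | ok > 1 + 1e-10, na.rm = TRUE))
    return("off-diagonal weights must lie in [0, 1]")
  TRUE
})

#' Maximum spanning tree of a connectivity matrix
#'
#' Acyclic connected subgraph with N - 1 edges whose total weight is maximal
#' among all spanning trees, extracted by Kruskal's algorithm on descending
#' weights with a deterministic lexicographic tie-break. The tree is the
#' carrier of the topological network metrics and of the edge-overlap
#' reliability index.
#'
#' @slot nodes channel labels (N).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight};
#'   N - 1 rows, \code{from < to} lexicographic order within each row.
#' @slot measure source connectivity measure label.
#' @slot band source band (or \code{NULL}).
#' @slot nTies number of weight ties encountered while sorting candidate
#'   edges; a high tie rate makes overlap comparisons fragile.
#'
#' @seealso [maxSpanningTree()], [mstMetrics()], [mstOverlap()]
#' @export
setClass("SpanningTree",
  representation(nodes = "character", edges = "data.frame",
                 measure = "character", band = "BandOrNULL",
                 nTies = "integer"))

setValidity("SpanningTree", function(object) {
  n <- length(object@nodes)
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("'edges' must have columns from, to, weight")
  if (n >= 2 && nrow(e) != n - 1L)
    return(sprintf("a spanning tree on %d nodes must have %d edges", n, n - 1L))
  if (!all(c(e$from, e$to) %in% object@nodes))
    return("edge endpoints must be tree nodes")
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = object@nodes)
  if (!igraph::is_connected(g)) return("tree is not connected")
  TRUE
})

#' End-to-end study report
#'
#' Container returned by [runStudy()]: the tidy per-recording scalar measure
#' table, the reliability table (temporal and state comparisons), the
#' spanning-tree overlap summary laid out band x (measure, comparison), and a
#' run manifest (seed, configuration, package version, warnings).
#'
#' @slot measureTable data.frame: subject, condition, band, measure, value.
#' @slot reliability data.frame: measure, band, comparison, n, icc, ci_low,
#'   ci_high, ci_method, category, plus the biomarker class per measure/band.
#' @slot overlap data.frame: band, measure, comparison, mean overlap percent,
#'   SD, and the equivalent mean edge count.
#' @slot groundTruth list with the generator's variance components and
#'   theoretical ICCs (empty when recordings were read from disk).
#' @slot manifest list: seed, configuration, timing, aggregated warnings.
#'
#' @seealso [runStudy()], [writeStudyReport()]
#' @export
setClass("StudyReport",
  representation(measureTable = "data.frame", reliability = "data.frame",
                 overlap = "data.frame", groundTruth = "list",
                 manifest = "list"))
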