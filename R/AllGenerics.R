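#' Region labels of an object
#'
#' @param x a SessionRecording, ConnectivityMatrix, BinaryNetwork or
#'   ModulePartition.
#' @return character vector of region names, in node-table order.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Adjacency matrix of a binary network
#'
#' @param x a [BinaryNetwork-class].
#' @return integer 0/1 matrix with region labels as dimnames.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Proportional density of a binary network
#'
#' @param x a [BinaryNetwork-class].
#' @return the target density delta at which the network was thresholded.
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' Number of undirected edges
#'
#' @param x a [BinaryNetwork-class].
#' @return integer edge count, equal to `round(delta * n(n-1)/2)`.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Fisher-z matrix of a connectivity object
#'
#' @param x a [ConnectivityMatrix-class].
#' @return symmetric numeric matrix of Fisher-z correlations, zero
#'   diagonal.
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' Module assignment of a partition
#'
#' @param x a [ModulePartition-class].
#' @return named character vector mapping region labels to module labels.
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' Fisher-z connectivity from a session recording
#'
#' Computes Pearson correlations between all pairs of region time courses
#' and applies the Fisher r-to-z transform, `z = atanh(r)`, off the
#' diagonal. `|r|` is clipped to `1 - 1e-7` beforehand so perfectly
#' (anti-)correlated pairs map to a large finite value rather than
#' infinity; the diagonal is forced to zero.
#'
#' @param x a [SessionRecording-class] (or a bare timepoints-by-regions
#'   matrix with column names).
#' @return a [ConnectivityMatrix-class].
#' @examples
#' rec <- generateCohort(synthConfig(nSubjects = 1, nRegions = 24,
#'   nTimepoints = 120, moduleSizes = rep(4L, 6)))[[1]]
#' cm <- correlate(rec)
#' range(zMatrix(cm))
#' @export
setGeneric("correlate", function(x) standardGeneric("correlate"))
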