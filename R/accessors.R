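#' @describeIn regionLabels region labels of a recording (column names of
#'   the data matrix).
#' @export
setMethod("regionLabels", "SessionRecording", function(x) colnames(x@data))

#' @describeIn regionLabels region labels of a connectivity matrix.
#' @export
setMethod("regionLabels", "ConnectivityMatrix", function(x) colnames(x@z))

#' @describeIn regionLabels region labels of a binary network.
#' @export
setMethod("regionLabels", "BinaryNetwork", function(x) colnames(x@adjacency))

#' @describeIn regionLabels region labels of a partition.
#' @export
setMethod("regionLabels", "ModulePartition", function(x) names(x@assignment))

#' @describeIn adjacencyMatrix adjacency of a binary network.
#' @export
setMethod("adjacencyMatrix", "BinaryNetwork", function(x) x@adjacency)

#' @describeIn networkDensity stated density of a binary network.
#' @export
setMethod("networkDensity", "BinaryNetwork", function(x) x@density)

#' @describeIn edgeCount edge count of a binary network.
#' @export
setMethod("edgeCount", "BinaryNetwork", function(x) x@edgeCount)

#' @describeIn zMatrix Fisher-z matrix of a connectivity object.
#' @export
setMethod("zMatrix", "ConnectivityMatrix", function(x) x@z)

#' @describeIn moduleAssignment module labels of a partition.
#' @export
setMethod("moduleAssignment", "ModulePartition", function(x) x@assignment)

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d subjects x 2 conditions x 4 sessions, %d regions, %d timepoints (TR %.1f s)\n",
    object@nSubjects, object@nRegions, object@nTimepoints, object@trSeconds))
  cat(sprintf("  modules: %s\n",
              paste(sprintf("%s=%d", names(object@moduleSizes),
                            object@moduleSizes), collapse = " ")))
  cat(sprintf(
    "  couplings: within %.2f, between %.2f, hub %.2f; AR(1) phi %.2f\n",
    object@withinCoupling, object@betweenCoupling, object@hubCoupling,
    object@arCoefficient))
  cat(sprintf(
    "  planted effects: condition %.2f, time %.2f; subject sd %.2f; seed %d\n",
    object@conditionEffect, object@timeEffect, object@subjectSd, object@seed))
})

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf(
    "SessionRecording %s / %s / %s: %d timepoints x %d regions\n",
    object@subjectId, object@condition, object@session,
    nrow(object@data), ncol(object@data)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- ncol(object@z)
  off <- object@z[upper.tri(object@z)]
  cat(sprintf("ConnectivityMatrix: %d x %d Fisher-z, off-diagonal range [%.3f, %.3f]\n",
              n, n, min(off), max(off)))
  if (length(object@provenance))
    cat(sprintf("  source: %s\n",
                paste(unlist(object@provenance), collapse = " / ")))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d nodes, %d edges (density %.2f)\n",
              ncol(object@adjacency), object@edgeCount, object@density))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf(
    "NullEnsemble: %d degree-preserving rewirings of a %d-node, %d-edge network (%d swaps/edge, seed %d)\n",
    object@nNulls, ncol(object@source@adjacency), object@source@edgeCount,
    object@rewiresPerEdge, object@seed))
})

setMethod("show", "ModulePartition", function(object) {
  tab <- table(object@assignment)
  cat(sprintf("ModulePartition (%s): %d regions in %d modules\n",
              object@source, length(object@assignment), length(tab)))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})
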