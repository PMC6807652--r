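#' @import methods
#' @importFrom stats cor pf pt sd var filter rnorm runif setNames p.adjust
#'   quantile aggregate
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

.CONDITIONS <- c("RW", "SR")
.SESSIONS <- c("T1000", "T1400", "T1800", "T2200")
.MODULES <- c("SMN", "VN", "FPN", "DMN", "LS", "CERB")

#' Configuration for the synthetic cohort generator
#'
#' Holds every parameter of the generative model used by
#' [generateCohort()]: the factorial design (subjects x 2 conditions x 4
#' sessions), the region/module layout, the coupling amplitudes of the
#' latent signal model, and the planted condition and time-of-day effects.
#' Construct instances with [synthConfig()], which supplies defaults
#' mirroring the emulated study design (13 subjects, 116 regions in six
#' functional modules, 840 timepoints at TR = 3 s).
#'
#' @slot nSubjects number of subjects.
#' @slot nRegions number of regions (nodes).
#' @slot nTimepoints number of timepoints per recording.
#' @slot trSeconds repetition time in seconds (metadata only).
#' @slot moduleSizes integer vector of module sizes summing to `nRegions`.
#' @slot moduleOf integer vector mapping each region to its module.
#' @slot regionLabels character vector of region names.
#' @slot withinCoupling amplitude of the shared module signal in each
#'   region (unitless, in `[0, 1)`).
#' @slot betweenCoupling coherence of the module latents with the global
#'   signal (unitless, in `[0, 1)`); controls inter-module correlation.
#' @slot hubCoupling amplitude of the shared hub latent in the designated
#'   hub regions (first region of each module); this is the hub-to-hub
#'   coupling that the time-of-day effect attenuates.
#' @slot hubBoost constant extra loading of each hub on its module's
#'   specific signal, making hubs the top-degree nodes of their modules.
#' @slot bridgeCoupling planted correlation between wired connector
#'   regions (see [connectorBlocks()]); each connector is wired to three
#'   partners in one other module, and the partner assignment rotates
#'   across sessions from degree-similar to degree-dissimilar module
#'   pairs, which is what lowers assortativity over the day.
#' @slot bridgeBlockSize number of connector regions per module
#'   (regions immediately after the hub in node-table order).
#' @slot blockContrast loading delta on the module-specific signal:
#'   positive for connector blocks in the two largest modules, negative
#'   in the two smallest, widening the degree contrast that the
#'   rotation mixes without touching between-module baselines.
#' @slot moduleContrast relative within-coupling multiplier contrast
#'   between modules: the two largest modules are `1 + moduleContrast`
#'   times more strongly coupled, the two smallest `1 - moduleContrast`
#'   times; makes node degree a stronger function of module membership.
#' @slot arCoefficient lag-1 autocorrelation of all latent and noise
#'   series, in `[0, 1)`.
#' @slot conditionEffect multiplicative reduction of `betweenCoupling`
#'   applied in the SR condition (>= 0); lengthens the characteristic path
#'   length at fixed density by removing inter-module shortcuts.
#' @slot timeEffect per-session multiplicative decrement of the hub
#'   couplings across T1000 -> T2200; drives assortativity down over the
#'   day.
#' @slot subjectSd between-subject coefficient of variation of the
#'   coupling parameters.
#' @slot seed integer RNG seed; identical (config, seed) pairs reproduce
#'   byte-identical cohorts.
#' @seealso [synthConfig()], [generateCohort()]
#' @export
setClass("SynthConfig", representation(
  nSubjects = "integer", nRegions = "integer", nTimepoints = "integer",
  trSeconds = "numeric", moduleSizes = "integer", moduleOf = "integer",
  regionLabels = "character", withinCoupling = "numeric",
  betweenCoupling = "numeric", hubCoupling = "numeric",
  hubBoost = "numeric", bridgeCoupling = "numeric",
  bridgeBlockSize = "integer", blockContrast = "numeric",
  moduleContrast = "numeric",
  arCoefficient = "numeric", conditionEffect = "numeric",
  timeEffect = "numeric", subjectSd = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (sum(object@moduleSizes) != object@nRegions)
    msg <- c(msg, "moduleSizes must sum to nRegions")
  if (any(object@moduleSizes < 2L))
    msg <- c(msg, "every module must contain at least 2 regions")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msg <- c(msg, "arCoefficient must lie in [0, 1)")
  if (object@withinCoupling < 0 || object@betweenCoupling < 0 ||
      object@hubCoupling < 0 || object@hubBoost < 0)
    msg <- c(msg, "couplings must be non-negative")
  if (object@withinCoupling >= 1 || object@betweenCoupling >= 1)
    msg <- c(msg, "withinCoupling and betweenCoupling must be < 1")
  if ((object@withinCoupling + object@hubBoost)^2 +
      object@hubCoupling^2 >= 1)
    msg <- c(msg,
             "(withinCoupling + hubBoost)^2 + hubCoupling^2 must be < 1")
  if (object@bridgeCoupling < 0 || object@bridgeCoupling > 0.6)
    msg <- c(msg, "bridgeCoupling must lie in [0, 0.6]")
  if (object@blockContrast < 0 || object@blockContrast >= 0.5)
    msg <- c(msg, "blockContrast must lie in [0, 0.5)")
  if (object@moduleContrast < 0 || object@moduleContrast >= 0.3)
    msg <- c(msg, "moduleContrast must lie in [0, 0.3)")
  if (object@bridgeBlockSize < 0L)
    msg <- c(msg, "bridgeBlockSize must be non-negative")
  if (object@conditionEffect < 0 || object@conditionEffect > 1)
    msg <- c(msg, "conditionEffect must lie in [0, 1]")
  if (object@timeEffect < 0 || object@timeEffect > 1/3)
    msg <- c(msg, "timeEffect must lie in [0, 1/3] so session couplings stay >= 0")
  if (length(object@regionLabels) != object@nRegions)
    msg <- c(msg, "regionLabels must have one entry per region")
  if (length(object@moduleOf) != object@nRegions)
    msg <- c(msg, "moduleOf must have one entry per region")
  if (length(msg)) msg else TRUE
})

#' A single region-by-time recording with its design factors
#'
#' One session of one subject under one condition: a numeric
#' timepoints-by-regions matrix whose column names are the region labels,
#' plus the three design factors (subject, condition RW/SR, session
#' T1000/T1400/T1800/T2200).
#'
#' @slot subjectId subject identifier.
#' @slot condition `"RW"` (rested wakefulness) or `"SR"` (sleep
#'   restriction).
#' @slot session one of `"T1000"`, `"T1400"`, `"T1800"`, `"T2200"`.
#' @slot data numeric matrix, timepoints x regions, column names are the
#'   region labels in node-table order.
#' @export
setClass("SessionRecording", representation(
  subjectId = "character", condition = "character", session = "character",
  data = "matrix"))

setValidity("SessionRecording", function(object) {
  msg <- character()
  if (!object@condition %in% .CONDITIONS)
    msg <- c(msg, "condition must be 'RW' or 'SR'")
  if (!object@session %in% .SESSIONS)
    msg <- c(msg, sprintf("session must be one of %s",
                          paste(.SESSIONS, collapse = ", ")))
  if (is.null(colnames(object@data)))
    msg <- c(msg, "data must carry region labels as column names")
  if (anyNA(object@data))
    msg <- c(msg, "data must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Symmetric Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations between region time courses, transformed
#' to Fisher z (atanh) off the diagonal; the diagonal is zero and `|r|` is
#' clipped to `1 - 1e-7` before the transform so every entry is finite.
#' Produced by [correlate()].
#'
#' @slot z symmetric numeric matrix of Fisher-z values, zero diagonal.
#' @slot provenance list with the source recording's subject, condition
#'   and session (empty when constructed from a bare matrix).
#' @export
setClass("ConnectivityMatrix",
         representation(z = "matrix", provenance = "list"))

setValidity("ConnectivityMatrix", function(object) {
  z <- object@z
  msg <- character()
  if (nrow(z) != ncol(z)) msg <- c(msg, "z must be square")
  if (!all(is.finite(z))) msg <- c(msg, "z must be finite everywhere")
  else {
    if (max(abs(z - t(z))) > 1e-10) msg <- c(msg, "z must be symmetric")
    if (any(diag(z) != 0)) msg <- c(msg, "diagonal of z must be zero")
  }
  if (is.null(colnames(z))) msg <- c(msg, "z must carry region labels")
  if (length(msg)) msg else TRUE
})

#' Undirected binary network at a stated density
#'
#' A 0/1 symmetric adjacency matrix with zero diagonal, obtained from a
#' [ConnectivityMatrix-class] by proportional thresholding: exactly
#' `round(density * n(n-1)/2)` strongest links are kept, so every network
#' at the same density has an identical edge count regardless of subject.
#'
#' @slot adjacency integer 0/1 matrix, symmetric, zero diagonal.
#' @slot density the target proportional density in (0, 1).
#' @slot edgeCount number of undirected edges.
#' @slot provenance list carried over from the source matrix.
#' @seealso [proportionalThreshold()], [densitySweep()]
#' @export
setClass("BinaryNetwork", representation(
  adjacency = "matrix", density = "numeric", edgeCount = "integer",
  provenance = "list"))

setValidity("BinaryNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency must be 0/1")
  if (any(diag(a) != 0)) msg <- c(msg, "self-loops are not allowed")
  if (!identical(a, t(a))) msg <- c(msg, "adjacency must be symmetric")
  if (sum(a) != 2L * object@edgeCount)
    msg <- c(msg, "edgeCount inconsistent with adjacency")
  if (is.null(colnames(a))) msg <- c(msg, "adjacency must carry region labels")
  if (length(msg)) msg else TRUE
})

#' Ensemble of degree-preserving random reference networks
#'
#' Maslov-Sneppen rewired copies of a source network, used as the random
#' reference in the small-world index. Every member has exactly the degree
#' sequence, edge count and density of the source; connectedness is not
#' guaranteed and downstream path-length code tolerates fragmented
#' members.
#'
#' @slot source the [BinaryNetwork-class] that was rewired.
#' @slot members list of rewired [BinaryNetwork-class] objects.
#' @slot nNulls number of members.
#' @slot rewiresPerEdge attempted double-edge swaps per edge.
#' @slot seed integer seed from which per-member seeds are derived.
#' @seealso [buildEnsemble()], [smallWorldSigma()]
#' @export
setClass("NullEnsemble", representation(
  source = "BinaryNetwork", members = "list", nNulls = "integer",
  rewiresPerEdge = "integer", seed = "integer"))

setValidity("NullEnsemble", function(object) {
  src_deg <- sort(colSums(object@source@adjacency))
  ok <- vapply(object@members, function(m)
    identical(sort(colSums(m@adjacency)), src_deg), logical(1))
  if (!all(ok)) "every member must preserve the source degree sequence"
  else TRUE
})

#' Assignment of regions to modules
#'
#' Maps each region to one community label, either the a priori six
#' functional modules (SMN, VN, FPN, DMN, LS, CERB) or a data-driven
#' partition found by modularity optimisation.
#'
#' @slot assignment named character vector, one module label per region.
#' @slot source `"a_priori_six"` or `"data_driven"`.
#' @export
setClass("ModulePartition",
         representation(assignment = "character", source = "character"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by region label")
  if (anyNA(object@assignment))
    msg <- c(msg, "every region must be assigned a module")
  if (!object@source %in% c("a_priori_six", "data_driven"))
    msg <- c(msg, "source must be 'a_priori_six' or 'data_driven'")
  if (length(msg)) msg else TRUE
})
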