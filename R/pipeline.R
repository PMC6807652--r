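.GLOBAL_MEASURES <- c("clustering", "transitivity", "modularity",
                      "path_length", "global_efficiency",
                      "local_efficiency", "small_world", "assortativity")
.LOCAL_MEASURES <- c("degree", "betweenness", "closeness", "eigenvector",
                     "pagerank", "k_coreness", "subgraph", "participation",
                     "diversity")

#' Long-form metric panel for a cohort
#'
#' Runs construction (correlation, Fisher z, proportional thresholding)
#' and metric extraction for every recording of a cohort across a
#' density sweep, returning the long-form table that is the unit of
#' statistical analysis: one row per (subject, condition, session,
#' density, node, measure).
#'
#' Modularity and the small-world index are opt-in (they are orders of
#' magnitude slower than the other measures: seeded Louvain restarts and
#' a rewired null ensemble per network); `nNulls` controls the ensemble
#' used for `small_world`.
#'
#' @param cohort list of [SessionRecording-class] objects.
#' @param densities density grid (default the canonical 25-step sweep).
#' @param globalMeasures subset of
#'   `c("clustering", "transitivity", "modularity", "path_length",
#'   "global_efficiency", "local_efficiency", "small_world",
#'   "assortativity")`, or `"all"`; `NULL` for none.
#' @param localMeasures subset of
#'   `c("degree", "betweenness", "closeness", "eigenvector", "pagerank",
#'   "k_coreness", "subgraph", "participation", "diversity")`, or
#'   `"all"`; `NULL` for none. Global rows carry `node = "global"`.
#' @param partition [ModulePartition-class] for participation/diversity;
#'   defaults to the packaged six-module partition for 116-region data.
#' @param absolute rank links by absolute correlation when thresholding.
#' @param nNulls,seed null-ensemble size and seed for `small_world`.
#' @return long-form data.frame with columns `subject`, `condition`,
#'   `session`, `density`, `node`, `measure`, `value`.
#' @export
computeMetricPanel <- function(cohort, densities = densityGrid(),
                               globalMeasures = c("clustering",
                                                  "transitivity",
                                                  "path_length",
                                                  "global_efficiency",
                                                  "assortativity"),
                               localMeasures = "degree",
                               partition = NULL, absolute = FALSE,
                               nNulls = 20, seed = 1L) {
  if (identical(globalMeasures, "all")) globalMeasures <- .GLOBAL_MEASURES
  if (identical(localMeasures, "all")) localMeasures <- .LOCAL_MEASURES
  stopifnot(all(globalMeasures %in% .GLOBAL_MEASURES),
            all(localMeasures %in% .LOCAL_MEASURES))
  need_part <- any(c("participation", "diversity") %in% localMeasures)
  rows <- vector("list", length(cohort))
  for (ri in seq_along(cohort)) {
    rec <- cohort[[ri]]
    cm <- correlate(rec)
    if (need_part && is.null(partition)) partition <- defaultPartition()
    per_density <- lapply(densities, function(d) {
      net <- proportionalThreshold(cm, d, absolute = absolute)
      out <- list()
      if (length(globalMeasures)) {
        vals <- .global_values(net, globalMeasures, nNulls, seed)
        out$global <- data.frame(density = d, node = "global",
                                 measure = names(vals),
                                 value = unname(vals),
                                 stringsAsFactors = FALSE)
      }
      if (length(localMeasures)) {
        lv <- .local_values(net, localMeasures, partition)
        out$local <- data.frame(density = d, node = rep(lv$node,
                                                        length(localMeasures)),
                                measure = rep(localMeasures,
                                              each = length(lv$node)),
                                value = unlist(lv$vals, use.names = FALSE),
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    block <- do.call(rbind, per_density)
    block$subject <- rec@subjectId
    block$condition <- rec@condition
    block$session <- rec@session
    rows[[ri]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject", "condition", "session", "density", "node", "measure",
          "value")]
}

.global_values <- function(net, measures, nNulls, seed) {
  vals <- numeric(0)
  if ("clustering" %in% measures)
    vals["clustering"] <- clusteringCoefficient(net)$mean
  if ("transitivity" %in% measures)
    vals["transitivity"] <- graphTransitivity(net)
  if ("modularity" %in% measures)
    vals["modularity"] <- modularityPartition(net, seed = seed)$Q
  if ("path_length" %in% measures)
    vals["path_length"] <- characteristicPathLength(net)$L
  if ("global_efficiency" %in% measures)
    vals["global_efficiency"] <- globalEfficiency(net)
  if ("local_efficiency" %in% measures)
    vals["local_efficiency"] <- localEfficiency(net)$mean
  if ("small_world" %in% measures)
    vals["small_world"] <- smallWorldSigma(
      net, buildEnsemble(net, nNulls = nNulls, seed = seed))
  if ("assortativity" %in% measures)
    vals["assortativity"] <- suppressWarnings(degreeAssortativity(net))
  vals
}

.local_values <- function(net, measures, partition) {
  vals <- lapply(measures, function(m) switch(
    m,
    degree = as.numeric(nodeDegree(net)),
    betweenness = as.numeric(nodeBetweenness(net)),
    closeness = as.numeric(nodeCloseness(net)),
    eigenvector = as.numeric(eigenvectorCentrality(net)),
    pagerank = as.numeric(pageRankCentrality(net)),
    k_coreness = as.numeric(kCoreness(net)),
    subgraph = as.numeric(subgraphCentrality(net)),
    participation = as.numeric(participationCoefficient(net, partition)),
    diversity = as.numeric(diversityCoefficient(net, partition))))
  list(node = regionLabels(net), vals = vals)
}

#' Run the full pipeline end to end
#'
#' Synthesis or ingestion, construction, metric extraction, group
#' statistics and output writing in one call. The input is either a
#' [SynthConfig-class] (a synthetic cohort is generated), a manifest CSV
#' path (recordings are read from disk after the design is validated),
#' or an in-memory cohort list. Outputs written to `outDir`:
#' `metric_panel.tsv`, `anova_results.tsv`, `roi_summary.tsv` (nodal
#' measures), `contrasts.tsv` (per-time RW vs SR contrasts for each
#' global measure), optionally the per-recording connectivity matrices
#' and per-density edge lists, and `run_log.txt` recording the package
#' version, seed and configuration, so a rerun with the same seed is
#' hash-identical.
#'
#' @param input a [SynthConfig-class], a manifest path, or a list of
#'   [SessionRecording-class].
#' @param outDir output directory.
#' @param densities density grid.
#' @param globalMeasures,localMeasures,partition,absolute,nNulls passed
#'   to [computeMetricPanel()].
#' @param alpha FDR level for [anovaPanel()] and [summarizeRoi()].
#' @param writeMatrices also write each recording's Fisher-z matrix and
#'   each network's edge list (verbose; off by default).
#' @param seed seed for modularity/null ensembles.
#' @return invisible list with `panel`, `anova`, `roi`, `contrasts` and
#'   the output paths.
#' @export
runPipeline <- function(input, outDir, densities = densityGrid(),
                        globalMeasures = c("clustering", "transitivity",
                                           "path_length",
                                           "global_efficiency",
                                           "assortativity"),
                        localMeasures = "degree", partition = NULL,
                        absolute = FALSE, nNulls = 20, alpha = 0.05,
                        writeMatrices = FALSE, seed = 1L) {
  cohort <- if (is(input, "SynthConfig")) generateCohort(input)
  else if (is.character(input)) readCohort(input)
  else input
  man <- data.frame(
    subject = vapply(cohort, function(r) r@subjectId, character(1)),
    condition = vapply(cohort, function(r) r@condition, character(1)),
    session = vapply(cohort, function(r) r@session, character(1)))
  .check_design(man)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  if (writeMatrices) {
    mdir <- file.path(outDir, "connectivity")
    edir <- file.path(outDir, "edges")
    dir.create(mdir, showWarnings = FALSE)
    dir.create(edir, showWarnings = FALSE)
    for (rec in cohort) {
      cm <- correlate(rec)
      stem <- paste(rec@subjectId, rec@condition, rec@session, sep = "_")
      writeMatrixTSV(cm, file.path(mdir, paste0(stem, "_z.tsv")))
      for (d in densities) {
        net <- proportionalThreshold(cm, d, absolute = absolute)
        write.table(edgeList(net, partition),
                    file.path(edir, sprintf("%s_d%.2f_edges.tsv", stem, d)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  panel <- computeMetricPanel(cohort, densities, globalMeasures,
                              localMeasures, partition, absolute,
                              nNulls, seed)
  write.table(panel, file.path(outDir, "metric_panel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  anova_res <- anovaPanel(panel, alpha = alpha)
  write.table(anova_res, file.path(outDir, "anova_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  roi <- NULL
  nodal <- anova_res[anova_res$node != "global", ]
  if (nrow(nodal)) {
    roi <- summarizeRoi(nodal, alpha = alpha)
    write.table(roi, file.path(outDir, "roi_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  contrasts <- NULL
  glob <- panel[panel$node == "global", ]
  if (nrow(glob)) {
    cc <- lapply(split(glob, list(glob$measure, glob$density), drop = TRUE),
                 function(cell) {
                   res <- posthocContrasts(cell$value, cell$subject,
                                           cell$condition, cell$session)
                   cbind(measure = cell$measure[1L],
                         density = cell$density[1L], res)
                 })
    contrasts <- do.call(rbind, c(cc, make.row.names = FALSE))
    write.table(contrasts, file.path(outDir, "contrasts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  log_lines <- c(
    sprintf("conngraph version: %s",
            as.character(utils::packageVersion("conngraph"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("densities: %s", paste(sprintf("%.2f", densities),
                                   collapse = " ")),
    sprintf("global measures: %s", paste(globalMeasures, collapse = " ")),
    sprintf("local measures: %s", paste(localMeasures, collapse = " ")),
    sprintf("alpha: %g", alpha),
    sprintf("recordings: %d", length(cohort)))
  if (is(input, "SynthConfig"))
    log_lines <- c(log_lines, sprintf(
      "synth: subjects=%d regions=%d timepoints=%d within=%.3f between=%.3f hub=%.3f ar=%.2f condition=%.3f time=%.3f subjectSd=%.3f seed=%d",
      input@nSubjects, input@nRegions, input@nTimepoints,
      input@withinCoupling, input@betweenCoupling, input@hubCoupling,
      input@arCoefficient, input@conditionEffect, input@timeEffect,
      input@subjectSd, input@seed))
  writeLines(log_lines, file.path(outDir, "run_log.txt"))

  invisible(list(panel = panel, anova = anova_res, roi = roi,
                 contrasts = contrasts, outDir = outDir))
}
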