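#' The packaged 116-region node table
#'
#' Loads the node table shipped with the package: the 116 regions of the
#' AAL parcellation (90 cortical and subcortical regions 1-90, 26
#' cerebellar regions 91-116) with a functional-module label for each
#' region and its hemisphere. The six modules are the sensorimotor network
#' (SMN), visual network (VN), frontoparietal network (FPN), default mode
#' network (DMN), subcortical/limbic system (LS) and cerebellar network
#' (CERB). The assignment of cortical regions to modules follows
#' conventional functional groupings; it is the package's own grouping,
#' intended for participation/diversity coefficients and module-level
#' summaries.
#'
#' @param path optional path to an alternative node-table CSV with columns
#'   `region_index`, `region_label`, `module`, `hemisphere`.
#' @return validated data.frame with those four columns.
#' @examples
#' tab <- aalNodeTable()
#' table(tab$module)
#' @export
aalNodeTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal116_modules.csv",
                        package = "conngraph", mustWork = TRUE)
  validateNodeTable(path)
}

#' Validate a node table
#'
#' Checks that a node table has 116 uniquely-labelled regions indexed
#' 1-116, module labels drawn from the six functional modules, and that
#' the cerebellar module is exactly regions 91-116.
#'
#' @param x path to a CSV file, or a data.frame with columns
#'   `region_index`, `region_label`, `module`, `hemisphere`.
#' @return the node table as a data.frame, invisibly validated.
#' @export
validateNodeTable <- function(x) {
  tab <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("region_index", "region_label", "module", "hemisphere")
  if (!all(need %in% names(tab)))
    stop("node table must have columns ", paste(need, collapse = ", "))
  if (nrow(tab) != 116L)
    stop("node table must have 116 rows, found ", nrow(tab))
  if (!identical(as.integer(tab$region_index), 1:116))
    stop("region_index must be 1..116 in order")
  if (anyDuplicated(tab$region_label))
    stop("region labels must be unique")
  bad <- setdiff(unique(tab$module), .MODULES)
  if (length(bad))
    stop("unknown module label(s): ", paste(bad, collapse = ", "))
  if (!all(tab$module[91:116] == "CERB") || any(tab$module[1:90] == "CERB"))
    stop("cerebellar module (CERB) must be exactly regions 91-116")
  tab
}

#' Module partition from a node table
#'
#' @param nodeTable a node table as returned by [aalNodeTable()], or any
#'   data.frame with `region_label` and `module` columns.
#' @return a [ModulePartition-class] with source `"a_priori_six"`.
#' @export
defaultPartition <- function(nodeTable = aalNodeTable()) {
  new("ModulePartition",
      assignment = setNames(as.character(nodeTable$module),
                            nodeTable$region_label),
      source = "a_priori_six")
}
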