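.fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

.correlate_matrix <- function(x, provenance = list()) {
  if (anyNA(x)) stop("input contains missing values")
  if (nrow(x) < 3L) stop("at least 3 timepoints are required")
  if (nrow(x) < 2L * ncol(x))
    warning(sprintf(
      "only %d timepoints for %d regions; correlation estimates may be unstable",
      nrow(x), ncol(x)))
  xc <- x - rep(colMeans(x), each = nrow(x))
  ss <- sqrt(colSums(xc^2))
  if (any(ss == 0))
    stop("constant-valued region series: ",
         paste(colnames(x)[ss == 0], collapse = ", "))
  r <- crossprod(xc) / tcrossprod(ss)     # Pearson via BLAS
  z <- .fisher_z(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2                     # enforce exact symmetry
  dimnames(z) <- list(colnames(x), colnames(x))
  new("ConnectivityMatrix", z = z, provenance = provenance)
}

#' @describeIn correlate connectivity of a session recording.
#' @export
setMethod("correlate", "SessionRecording", function(x)
  .correlate_matrix(x@data, provenance = list(subject = x@subjectId,
                                              condition = x@condition,
                                              session = x@session)))

#' @describeIn correlate connectivity of a bare timepoints-by-regions
#'   matrix with region labels as column names.
#' @export
setMethod("correlate", "matrix", function(x) {
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("R%03d", seq_len(ncol(x)))
  .correlate_matrix(x)
})

#' Threshold a connectivity matrix to a binary network of exact density
#'
#' Keeps exactly `k = round(delta * n(n-1)/2)` upper-triangle entries
#' with the largest Fisher-z values (rounding half away from zero),
#' symmetrises, and zeroes the diagonal, so every network at the same
#' density has the identical edge count -- the prerequisite for comparing
#' graph measures within or between subjects. Ties at the cut value are
#' broken deterministically by ascending (row, column) index order.
#'
#' By default links are ranked by signed z, i.e. the strongest positive
#' correlations survive; `absolute = TRUE` ranks by `|z|` instead.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param density target proportional density delta in (0, 1).
#' @param absolute rank links by absolute rather than signed z.
#' @return a [BinaryNetwork-class] with exactly `k` edges.
#' @examples
#' cm <- correlate(matrix(rnorm(2000), 100, 20))
#' net <- proportionalThreshold(cm, 0.15)
#' edgeCount(net)  # round(0.15 * 190) = 29
#' @export
proportionalThreshold <- function(cm, density, absolute = FALSE) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density >= 1)
    stop("density must be a single value in (0, 1)")
  n <- ncol(cm@z)
  npairs <- n * (n - 1) / 2
  k <- .round_half_up(density * npairs)
  if (k < 1L) stop("density too low: no edges would be kept")
  pairs <- .upper_pairs(n)
  w <- cm@z[pairs]
  if (absolute) w <- abs(w)
  # stable sort: ties resolved by ascending (row, col) order of `pairs`
  keep <- sort.list(w, decreasing = TRUE, method = "radix")[seq_len(k)]
  adj <- matrix(0L, n, n, dimnames = dimnames(cm@z))
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  .new_network(adj, density, provenance = cm@provenance)
}

#' The inclusive density grid used for a sweep
#'
#' Built by integer stepping (`start + i * step`, rounded to 2 decimals)
#' to avoid floating-point drift; `(0.06, 0.30, 0.01)` yields exactly the
#' 25 canonical densities.
#'
#' @param start,stop,step grid limits and increment.
#' @return numeric vector of densities.
#' @export
densityGrid <- function(start = 0.06, stop = 0.30, step = 0.01) {
  if (step <= 0) stop("step must be positive")
  if (start > stop) stop("start must not exceed stop")
  round(start + step * seq.int(0L, floor((stop - start) / step + 1e-9)), 2L)
}

#' Threshold one connectivity matrix across a density sweep
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param start,stop,step inclusive density grid (defaults 0.06 to 0.30
#'   in steps of 0.01, i.e. 25 densities).
#' @param absolute passed to [proportionalThreshold()].
#' @return named list of [BinaryNetwork-class], one per density. Because
#'   the tie-break is deterministic, the edge set at a lower density is
#'   always a subset of the edge set at a higher one.
#' @export
densitySweep <- function(cm, start = 0.06, stop = 0.30, step = 0.01,
                         absolute = FALSE) {
  grid <- densityGrid(start, stop, step)
  # one shared ranking: nested edge sets by construction, and ~10x
  # cheaper than independent thresholding across a 25-density sweep
  n <- ncol(cm@z)
  npairs <- n * (n - 1) / 2
  pairs <- .upper_pairs(n)
  w <- cm@z[pairs]
  if (absolute) w <- abs(w)
  ord <- sort.list(w, decreasing = TRUE, method = "radix")
  nets <- lapply(grid, function(d) {
    k <- .round_half_up(d * npairs)
    if (k < 1L) stop("density too low: no edges would be kept")
    adj <- matrix(0L, n, n, dimnames = dimnames(cm@z))
    adj[pairs[ord[seq_len(k)], , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    .new_network(adj, d, provenance = cm@provenance)
  })
  names(nets) <- sprintf("%.2f", grid)
  nets
}

#' Edge list of a binary network
#'
#' Two-column representation (`region_a`, `region_b`) of the undirected
#' edges, suitable for connectogram tools; optionally annotated with the
#' module of each endpoint and whether the edge is within or between
#' modules.
#'
#' @param net a [BinaryNetwork-class].
#' @param partition optional [ModulePartition-class] for module
#'   annotation.
#' @return data.frame with one row per undirected edge.
#' @export
edgeList <- function(net, partition = NULL) {
  stopifnot(is(net, "BinaryNetwork"))
  idx <- which(upper.tri(net@adjacency) & net@adjacency == 1L,
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  labs <- regionLabels(net)
  out <- data.frame(region_a = labs[idx[, 1L]], region_b = labs[idx[, 2L]],
                    stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    mod <- moduleAssignment(partition)
    out$module_a <- unname(mod[out$region_a])
    out$module_b <- unname(mod[out$region_b])
    out$type <- ifelse(out$module_a == out$module_b, "within", "between")
  }
  out
}

#' Write / read a labelled square matrix as TSV
#'
#' Serialisation used for connectivity and adjacency matrices: a
#' tab-separated table with region labels as the header row.
#'
#' @param m matrix (or [ConnectivityMatrix-class] /
#'   [BinaryNetwork-class], whose matrix slot is taken).
#' @param file path.
#' @return `readMatrixTSV` returns the matrix with dimnames restored.
#' @export
writeMatrixTSV <- function(m, file) {
  if (is(m, "ConnectivityMatrix")) m <- m@z
  if (is(m, "BinaryNetwork")) m <- m@adjacency
  write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(file) {
  m <- as.matrix(read.delim(file, check.names = FALSE))
  rownames(m) <- colnames(m)
  m
}
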