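#' Nodal degree
#'
#' @param net a [BinaryNetwork-class].
#' @return named integer vector, one entry per region.
#' @export
nodeDegree <- function(net) {
  setNames(as.integer(colSums(net@adjacency)), regionLabels(net))
}

#' Betweenness centrality, normalised
#'
#' Fraction of all shortest paths passing through each node (Brandes
#' accumulation with fractional credit for tied paths), normalised by
#' `(n-1)(n-2)/2` so values are comparable across densities.
#'
#' @param net a [BinaryNetwork-class].
#' @return named numeric vector in `[0, 1]`.
#' @export
nodeBetweenness <- function(net) {
  n <- ncol(net@adjacency)
  b <- igraph::betweenness(.as_igraph(net), directed = FALSE)
  setNames(b / ((n - 1) * (n - 2) / 2), regionLabels(net))
}

#' Closeness centrality with component scaling
#'
#' Within its component, node i scores `(n_c - 1) / sum_j d(i, j)`; to
#' keep fragmented graphs comparable the value is then scaled by
#' `(n_c - 1) / (n - 1)` (Wasserman-Faust), where `n_c` is the size of
#' i's component. Isolated nodes score 0.
#'
#' @param net a [BinaryNetwork-class].
#' @return named numeric vector.
#' @export
nodeCloseness <- function(net) {
  d <- igraph::distances(.as_igraph(net))
  n <- ncol(d)
  vals <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (!length(reach)) return(0)
    nc <- length(reach) + 1L
    ((nc - 1) / sum(reach)) * ((nc - 1) / (n - 1))
  }, numeric(1))
  setNames(vals, regionLabels(net))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix (symmetric
#' eigendecomposition), oriented non-negative and scaled to unit
#' Euclidean norm.
#'
#' @param net a [BinaryNetwork-class] with at least one edge.
#' @return named numeric vector with `sum(v^2) = 1`.
#' @export
eigenvectorCentrality <- function(net) {
  if (net@edgeCount < 1L)
    stop("eigenvector centrality is undefined for an edgeless graph")
  e <- eigen(net@adjacency, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)               # clip tiny negative round-off
  v <- v / sqrt(sum(v^2))
  setNames(v, regionLabels(net))
}

#' PageRank centrality
#'
#' Power iteration on the damped column-stochastic transition matrix
#' with uniform teleport: `p <- (1-d)/n + d (W p + dangling_mass / n)`,
#' where dangling (isolated) nodes redistribute their mass uniformly.
#' Iterates to an L1 tolerance of 1e-12; values sum to 1.
#'
#' @param net a [BinaryNetwork-class].
#' @param damping damping factor (default 0.85).
#' @return named numeric vector summing to 1.
#' @export
pageRankCentrality <- function(net, damping = 0.85) {
  adj <- net@adjacency
  n <- ncol(adj)
  deg <- colSums(adj)
  dangling <- deg == 0
  W <- adj / ifelse(deg == 0, 1, deg)[col(adj)]   # column-stochastic
  p <- rep(1 / n, n)
  repeat {
    p_new <- (1 - damping) / n +
      damping * (as.vector(W %*% p) + sum(p[dangling]) / n)
    if (sum(abs(p_new - p)) < 1e-12) { p <- p_new; break }
    p <- p_new
  }
  setNames(p / sum(p), regionLabels(net))
}

#' K-coreness centrality
#'
#' Core number of each node: the largest k such that the node survives
#' in the maximal subgraph with all degrees >= k (iterative minimum-
#' degree peeling).
#'
#' @param net a [BinaryNetwork-class].
#' @return named integer vector.
#' @export
kCoreness <- function(net) {
  setNames(as.integer(igraph::coreness(.as_igraph(net))),
           regionLabels(net))
}

#' Subgraph centrality
#'
#' Diagonal of the adjacency-matrix exponential: the count of closed
#' walks through each node, weighted `1/length!`. Computed exactly via
#' the symmetric eigendecomposition, `SC_i = sum_j V_ij^2 exp(lambda_j)`.
#' An isolated node scores `exp(0) = 1`.
#'
#' @param net a [BinaryNetwork-class].
#' @return named numeric vector, every entry >= 1.
#' @export
subgraphCentrality <- function(net) {
  e <- eigen(net@adjacency, symmetric = TRUE)
  sc <- as.vector(e$vectors^2 %*% exp(e$values))
  setNames(sc, regionLabels(net))
}

.partition_index <- function(net, partition) {
  mod <- moduleAssignment(partition)
  if (!all(regionLabels(net) %in% names(mod)))
    stop("partition does not cover all regions of the network")
  match(mod[regionLabels(net)], unique(mod[regionLabels(net)]))
}

#' Participation coefficient
#'
#' `1 - sum_m (k_im / k_i)^2`: 0 when all of a node's links stay inside
#' one module, approaching `1 - 1/m` when they spread evenly over m
#' modules. Isolated nodes score 0. The a priori six-module partition is
#' the default; pass a data-driven partition from
#' [modularityPartition()] to switch.
#'
#' @param net a [BinaryNetwork-class].
#' @param partition a [ModulePartition-class] covering the network's
#'   regions.
#' @return named numeric vector in `[0, 1]`.
#' @export
participationCoefficient <- function(net, partition = defaultPartition()) {
  pidx <- .partition_index(net, partition)
  adj <- net@adjacency
  deg <- colSums(adj)
  # k_im: links of node i into module m
  kim <- t(rowsum(adj, pidx))            # nodes x modules
  frac2 <- (kim / ifelse(deg == 0, 1, deg))^2
  vals <- ifelse(deg == 0, 0, 1 - rowSums(frac2))
  setNames(vals, regionLabels(net))
}

#' Diversity coefficient
#'
#' Shannon entropy of a node's link distribution across modules,
#' normalised by `log(m)` so 0 means all links in one module and 1 means
#' an even spread over all m modules. Edges carry unit weight (binary
#' graphs).
#'
#' @inheritParams participationCoefficient
#' @return named numeric vector in `[0, 1]`.
#' @export
diversityCoefficient <- function(net, partition = defaultPartition()) {
  pidx <- .partition_index(net, partition)
  m <- length(unique(pidx))
  adj <- net@adjacency
  deg <- colSums(adj)
  kim <- t(rowsum(adj, pidx))
  frac <- kim / ifelse(deg == 0, 1, deg)
  ent <- -rowSums(ifelse(frac > 0, frac * log(frac), 0))
  vals <- ifelse(deg == 0, 0, ent / log(m))
  setNames(vals, regionLabels(net))
}

#' All nodal centralities of one network
#'
#' @param net a [BinaryNetwork-class].
#' @param partition partition for participation and diversity (default
#'   the packaged six-module partition when the regions match, otherwise
#'   required).
#' @param damping PageRank damping factor.
#' @return data.frame with one row per region and one column per
#'   measure (`degree`, `betweenness`, `closeness`, `eigenvector`,
#'   `pagerank`, `k_coreness`, `subgraph`, `participation`,
#'   `diversity`).
#' @export
localMetrics <- function(net, partition = defaultPartition(),
                         damping = 0.85) {
  data.frame(
    node = regionLabels(net),
    degree = as.numeric(nodeDegree(net)),
    betweenness = as.numeric(nodeBetweenness(net)),
    closeness = as.numeric(nodeCloseness(net)),
    eigenvector = as.numeric(eigenvectorCentrality(net)),
    pagerank = as.numeric(pageRankCentrality(net, damping)),
    k_coreness = as.numeric(kCoreness(net)),
    subgraph = as.numeric(subgraphCentrality(net)),
    participation = as.numeric(participationCoefficient(net, partition)),
    diversity = as.numeric(diversityCoefficient(net, partition)),
    stringsAsFactors = FALSE)
}
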