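#' Clustering coefficient
#'
#' Watts-Strogatz local clustering: for node i with degree `k_i`,
#' `2 T_i / (k_i (k_i - 1))` where `T_i` counts triangles through i;
#' nodes with degree < 2 score 0.
#'
#' @param net a [BinaryNetwork-class].
#' @return list with `node` (named per-node values) and `mean`.
#' @export
clusteringCoefficient <- function(net) {
  g <- .as_igraph(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(cc) <- regionLabels(net)
  list(node = cc, mean = mean(cc))
}

#' Transitivity (global clustering)
#'
#' `3 * triangles / connected triples`; defined as 0 when the graph has
#' no connected triple.
#'
#' @param net a [BinaryNetwork-class].
#' @return single value in `[0, 1]`.
#' @export
graphTransitivity <- function(net) {
  tr <- igraph::transitivity(.as_igraph(net), type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes
#' with a finite distance (BFS all-pairs). When the network is
#' fragmented, unreachable pairs are dropped from the average and the
#' `fragmented` flag is set -- so a very fragmented network can have a
#' deceptively short L; [globalEfficiency()] is the fragmentation-safe
#' companion.
#'
#' @param net a [BinaryNetwork-class] with at least one edge.
#' @return list with `L` and logical `fragmented`.
#' @export
characteristicPathLength <- function(net) {
  if (net@edgeCount < 1L) stop("path length is undefined for an edgeless network")
  d <- igraph::distances(.as_igraph(net))
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  list(L = mean(off[finite]), fragmented = !all(finite))
}

#' Global efficiency
#'
#' Mean of `1 / d(i, j)` over all ordered pairs, with `1/Inf = 0`, which
#' handles fragmentation without any flag.
#'
#' @param net a [BinaryNetwork-class].
#' @return value in `[0, 1]`.
#' @export
globalEfficiency <- function(net) {
  n <- ncol(net@adjacency)
  if (n < 2L) return(0)
  d <- igraph::distances(.as_igraph(net))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (0 for degree < 2), and the mean over nodes.
#'
#' @param net a [BinaryNetwork-class].
#' @return list with `node` and `mean`.
#' @export
localEfficiency <- function(net) {
  adj <- net@adjacency
  n <- ncol(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2L) next
    sub <- adj[nb, nb, drop = FALSE]
    vals[i] <- globalEfficiency(.new_network(sub, density = net@density))
  }
  names(vals) <- regionLabels(net)
  list(node = vals, mean = mean(vals))
}

#' Modularity and data-driven partition
#'
#' Louvain optimisation of Newman-Girvan modularity at resolution 1,
#' repeated over `restarts` seeded runs; the partition with the highest Q
#' wins, ties going to the lexicographically smallest membership vector,
#' so the result is reproducible despite the heuristic's
#' order-dependence.
#'
#' @param net a [BinaryNetwork-class] with at least one edge.
#' @param seed RNG seed for the restarts.
#' @param restarts number of seeded Louvain runs (default 10).
#' @return list with `Q` and a [ModulePartition-class] (source
#'   `"data_driven"`, labels `"C1"`, `"C2"`, ...).
#' @export
modularityPartition <- function(net, seed = 1L, restarts = 10) {
  if (net@edgeCount < 1L) stop("modularity needs at least one edge")
  g <- .as_igraph(net)
  best_q <- -Inf
  best_m <- NULL
  for (r in seq_len(restarts)) {
    memb <- withr::with_seed(.derive_seed(seed, 300000 + r),
                             igraph::membership(igraph::cluster_louvain(g)))
    q <- igraph::modularity(g, memb)
    better <- q > best_q + 1e-12 ||
      (abs(q - best_q) <= 1e-12 && !is.null(best_m) &&
         .lex_less(memb, best_m))
    if (is.null(best_m) || better) { best_q <- q; best_m <- memb }
  }
  canon <- match(best_m, unique(best_m))   # canonical label order
  assignment <- setNames(paste0("C", canon), regionLabels(net))
  list(Q = best_q,
       partition = new("ModulePartition", assignment = assignment,
                       source = "data_driven"))
}

.lex_less <- function(a, b) {
  a <- match(a, unique(a)); b <- match(b, unique(b))
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Degree assortativity
#'
#' Newman's degree-degree Pearson correlation over edge endpoints (both
#' orientations). For a regular graph the endpoint degree variance is
#' zero and the coefficient is undefined: `NA` is returned with a warning
#' rather than an error, so density sweeps do not abort.
#'
#' @param net a [BinaryNetwork-class].
#' @return value in `[-1, 1]`, or `NA` for a degree-regular graph.
#' @export
degreeAssortativity <- function(net) {
  deg <- colSums(net@adjacency)
  idx <- which(upper.tri(net@adjacency) & net@adjacency == 1L,
               arr.ind = TRUE)
  d1 <- deg[idx[, 1L]]; d2 <- deg[idx[, 2L]]
  x <- c(d1, d2); y <- c(d2, d1)      # both orientations
  if (var(x) == 0) {
    warning("degree-regular graph: assortativity is undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Small-world index sigma
#'
#' Classical sigma: `(C / <C_null>) / (L / <L_null>)` with C the mean
#' clustering coefficient, L the characteristic path length
#' (finite-pair convention, also for fragmented null members), and the
#' null means taken over a degree-preserving rewired ensemble. Values
#' substantially above 1 indicate high clustering with near-random path
#' length. The index inherits the known weaknesses of sigma (density
#' dependence, lattice misdiagnosis); it is computed here because it is
#' the classical choice, with those caveats documented.
#'
#' @param net a [BinaryNetwork-class].
#' @param ensemble a [NullEnsemble-class] built from `net`.
#' @return sigma (unitless).
#' @export
smallWorldSigma <- function(net, ensemble) {
  stopifnot(is(ensemble, "NullEnsemble"))
  C <- clusteringCoefficient(net)$mean
  L <- characteristicPathLength(net)$L
  Cn <- mean(vapply(ensemble@members,
                    function(m) clusteringCoefficient(m)$mean, numeric(1)))
  Ln <- mean(vapply(ensemble@members,
                    function(m) characteristicPathLength(m)$L, numeric(1)))
  if (Cn == 0) stop("null clustering is zero: sigma is undefined")
  (C / Cn) / (L / Ln)
}

#' All global measures of one network
#'
#' Convenience panel: clustering, transitivity, modularity Q,
#' characteristic path length (plus fragmentation flag), global and local
#' efficiency, assortativity, and -- when an ensemble is supplied or
#' `nNulls > 0` -- the small-world sigma.
#'
#' @param net a [BinaryNetwork-class].
#' @param ensemble optional [NullEnsemble-class]; if `NULL` and
#'   `nNulls > 0` one is built internally.
#' @param nNulls,rewiresPerEdge,seed ensemble parameters when built
#'   internally; `nNulls = 0` skips sigma (returned as `NA`).
#' @return one-row data.frame of the eight global measures plus
#'   `density` and `fragmented`.
#' @export
globalMetrics <- function(net, ensemble = NULL, nNulls = 20,
                          rewiresPerEdge = 10, seed = 1L) {
  if (is.null(ensemble) && nNulls > 0)
    ensemble <- buildEnsemble(net, nNulls, rewiresPerEdge, seed)
  cpl <- characteristicPathLength(net)
  mod <- modularityPartition(net, seed = seed)
  sigma <- if (is.null(ensemble)) NA_real_ else smallWorldSigma(net, ensemble)
  data.frame(
    density = net@density,
    clustering = clusteringCoefficient(net)$mean,
    transitivity = graphTransitivity(net),
    modularity = mod$Q,
    path_length = cpl$L,
    global_efficiency = globalEfficiency(net),
    local_efficiency = localEfficiency(net)$mean,
    small_world = sigma,
    assortativity = degreeAssortativity(net),
    fragmented = cpl$fragmented)
}
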