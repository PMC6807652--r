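#' Degree-preserving rewiring of a binary network
#'
#' Maslov-Sneppen double-edge swap: repeatedly picks two edges (a,b),
#' (c,d) and replaces them with (a,d), (c,b) when doing so creates no
#' self-loop and no multi-edge. Exactly
#' `rewiresPerEdge * edgeCount` swaps are *attempted* (attempt counting
#' gives bounded runtime); the degree sequence is preserved exactly.
#' Graphs that admit no legal swap (for example a star) are returned
#' unchanged with a warning.
#'
#' @param net a [BinaryNetwork-class] with at least 2 edges.
#' @param rewiresPerEdge attempted swaps per edge (default 10).
#' @param seed RNG seed for this rewiring.
#' @return a rewired [BinaryNetwork-class] with the same degree sequence,
#'   edge count and density as `net`.
#' @seealso [buildEnsemble()]
#' @export
rewireNetwork <- function(net, rewiresPerEdge = 10, seed = 1L) {
  stopifnot(is(net, "BinaryNetwork"))
  if (net@edgeCount < 2L)
    stop("rewiring needs at least 2 edges")
  adj <- net@adjacency
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  m <- nrow(edges)
  attempts <- as.integer(.round_half_up(rewiresPerEdge * m))
  swapped <- 0L
  if (attempts > 0L) {
    withr::with_seed(as.integer(seed), {
      pick <- matrix(sample.int(m, 2L * attempts, replace = TRUE),
                     ncol = 2L)
      flip <- runif(attempts) < 0.5
      for (t in seq_len(attempts)) {
        e1 <- pick[t, 1L]; e2 <- pick[t, 2L]
        if (e1 == e2) next
        a <- edges[e1, 1L]; b <- edges[e1, 2L]
        c <- edges[e2, 1L]; d <- edges[e2, 2L]
        # randomise which endpoints are exchanged so both swap
        # orientations are reachable
        if (flip[t]) { tmp <- c; c <- d; d <- tmp }
        if (a == c || a == d || b == c || b == d) next
        if (adj[a, d] == 1L || adj[c, b] == 1L) next
        adj[a, b] <- adj[b, a] <- 0L
        adj[c, d] <- adj[d, c] <- 0L
        adj[a, d] <- adj[d, a] <- 1L
        adj[c, b] <- adj[b, c] <- 1L
        edges[e1, ] <- c(min(a, d), max(a, d))
        edges[e2, ] <- c(min(c, b), max(c, b))
        swapped <- swapped + 1L
      }
    })
  }
  if (swapped == 0L && attempts > 0L)
    warning("no legal double-edge swap was found; returning the network unchanged")
  .new_network(adj, net@density, provenance = net@provenance)
}

#' Build an ensemble of degree-preserving null networks
#'
#' `nNulls` independent rewirings of the source network, each with its
#' own RNG stream derived from `(seed, member index)`, so the ensemble is
#' reproducible and members are exchangeable. Used as the random
#' reference for [smallWorldSigma()]. Members are not guaranteed to be
#' connected; path-length code uses the finite-pair convention.
#'
#' @param net a [BinaryNetwork-class].
#' @param nNulls ensemble size (default 20).
#' @param rewiresPerEdge attempted swaps per edge per member (default 10).
#' @param seed master seed.
#' @return a [NullEnsemble-class].
#' @export
buildEnsemble <- function(net, nNulls = 20, rewiresPerEdge = 10, seed = 1L) {
  stopifnot(is(net, "BinaryNetwork"))
  if (nNulls < 1L) stop("nNulls must be at least 1")
  members <- lapply(seq_len(nNulls), function(i)
    rewireNetwork(net, rewiresPerEdge,
                  seed = .derive_seed(seed, 200000 + i)))
  new("NullEnsemble", source = net, members = members,
      nNulls = as.integer(nNulls),
      rewiresPerEdge = as.integer(rewiresPerEdge), seed = as.integer(seed))
}
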