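# Independent brute-force oracles, deliberately implemented with
# different algorithms than the package (Floyd-Warshall instead of BFS,
# explicit triple/walk enumeration, path counting by distance recursion)
# so that agreement is a genuine cross-check.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  list(L = mean(off[is.finite(off)]), fragmented = any(is.infinite(off)))
}

oracle_global_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(adj) * (nrow(adj) - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# triangles through each node by explicit triple enumeration
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    k <- sum(adj[i, ])
    if (k < 2) return(0)
    tri <- 0
    nb <- which(adj[i, ] == 1)
    for (a in seq_along(nb)) for (b in seq_len(a - 1))
      if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (adj[i, j] == 1 && adj[j, k] == 1) {
      triples <- triples + 1
      if (adj[i, k] == 1) triangles <- triangles + 1
    }
  }
  if (triples == 0) 0 else triangles / triples
}

# shortest-path counts via recursion over distance shells
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  for (len in seq_len(max(maxd, 1))) {
    idx <- which(d == len, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      pred <- which(adj[, j] == 1 & d[i, ] == len - 1)
      sigma[i, j] <- sum(sigma[i, pred])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  b <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || i == v || j == v) next
      if (!is.finite(d[i, j]) || sigma[i, j] == 0) next
      if (is.finite(d[i, v]) && is.finite(d[v, j]) &&
          d[i, v] + d[v, j] == d[i, j])
        tot <- tot + sigma[i, v] * sigma[v, j] / sigma[i, j]
    }
    b[v] <- tot / 2   # undirected: each unordered pair counted twice
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (!length(reach)) return(0)
    nc <- length(reach) + 1
    ((nc - 1) / sum(reach)) * ((nc - 1) / (n - 1))
  }, numeric(1))
}

# core numbers by repeated deletion
oracle_coreness <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- colSums(adj[alive, alive, drop = FALSE])
      drop_i <- which(deg < k)
      if (!length(drop_i) || !any(alive)) break
      alive[which(alive)[drop_i]] <- FALSE
    }
    core[alive] <- k
    if (!any(alive)) break
  }
  core
}

# truncated walk sum sum_l (A^l)_ii / l!
oracle_subgraph <- function(adj, lmax = 30) {
  n <- nrow(adj)
  out <- rep(1, n)       # l = 0 term
  P <- diag(n)
  fact <- 1
  for (l in seq_len(lmax)) {
    P <- P %*% adj
    fact <- fact * l
    out <- out + diag(P) / fact
  }
  out
}

# power iteration on A + I: same eigenvectors, but avoids the
# oscillation of plain iteration on bipartite graphs
oracle_eigenvector <- function(adj, iters = 50000) {
  B <- adj + diag(nrow(adj))
  v <- rep(1, nrow(adj))
  for (i in seq_len(iters)) {
    v2 <- B %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-14) break
    v <- v2
  }
  as.vector(v)
}

oracle_pagerank <- function(adj, damping = 0.85, iters = 500) {
  n <- nrow(adj)
  deg <- colSums(adj)
  p <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    pnew <- rep((1 - damping) / n, n)
    for (j in seq_len(n)) {
      if (deg[j] == 0) pnew <- pnew + damping * p[j] / n
      else {
        nb <- which(adj[, j] == 1)
        pnew[nb] <- pnew[nb] + damping * p[j] / deg[j]
      }
    }
    p <- pnew
  }
  p / sum(p)
}

oracle_assortativity <- function(adj) {
  deg <- colSums(adj)
  ends <- which(adj == 1, arr.ind = TRUE)   # both orientations
  stats::cor(deg[ends[, 1]], deg[ends[, 2]])
}

oracle_participation <- function(adj, mod) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    k <- sum(adj[i, ])
    if (k == 0) return(0)
    1 - sum(vapply(unique(mod), function(m)
      (sum(adj[i, mod == m]) / k)^2, numeric(1)))
  }, numeric(1))
}

oracle_diversity <- function(adj, mod) {
  n <- nrow(adj)
  mlev <- unique(mod)
  vapply(seq_len(n), function(i) {
    k <- sum(adj[i, ])
    if (k == 0) return(0)
    p <- vapply(mlev, function(m) sum(adj[i, mod == m]) / k, numeric(1))
    p <- p[p > 0]
    -sum(p * log(p)) / log(length(mlev))
  }, numeric(1))
}

# random test graph with labelled nodes
random_network <- function(n, p = 0.4, seed = 1, density = 0.3) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  conngraph:::.new_network(adj, density)
}

# named adjacency from an explicit edge list (1-based node indices)
net_from_edges <- function(n, edges, density = 0.3) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  dimnames(adj) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  conngraph:::.new_network(adj, density)
}

complete_net <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L
  dimnames(adj) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  conngraph:::.new_network(adj, 0.99)
}

star_net <- function(nleaves) {
  n <- nleaves + 1
  net_from_edges(n, lapply(2:n, function(j) c(1, j)))
}

ring_net <- function(n, k = 2) {
  edges <- list()
  for (i in seq_len(n)) for (o in seq_len(k / 2))
    edges <- c(edges, list(c(i, (i + o - 1) %% n + 1)))
  net_from_edges(n, edges)
}
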