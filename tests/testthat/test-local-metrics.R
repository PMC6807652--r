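test_that("degree closed forms and the handshake lemma", {
  expect_equal(unname(nodeDegree(complete_net(5))), rep(4L, 5))
  s6 <- star_net(6)
  expect_equal(unname(nodeDegree(s6)), c(6L, rep(1L, 6)))
  net <- random_network(15, p = 0.3, seed = 2)
  expect_equal(sum(nodeDegree(net)), 2L * edgeCount(net))
})

test_that("betweenness: star centre is 1, cycle is symmetric", {
  s6 <- star_net(6)
  b <- nodeBetweenness(s6)
  expect_equal(unname(b[1]), 1)
  expect_equal(unname(b[-1]), rep(0, 6))
  b5 <- nodeBetweenness(ring_net(5, 2))
  expect_equal(unname(b5), rep(b5[[1]], 5))
})

test_that("closeness: complete graph is 1, path midpoints beat endpoints,
           disjoint components are scaled", {
  expect_equal(unname(nodeCloseness(complete_net(5))), rep(1, 5))
  p3 <- net_from_edges(3, list(c(1, 2), c(2, 3)))
  cl <- nodeCloseness(p3)
  expect_gt(cl[[2]], cl[[1]])
  two_k3 <- net_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                   c(4, 5), c(4, 6), c(5, 6)))
  # within-component closeness 1, scaled by (3-1)/(6-1)
  expect_equal(unname(nodeCloseness(two_k3)), rep(2 / 5, 6))
})

test_that("eigenvector centrality is unit norm, uniform on regular graphs,
           centre-dominant on stars", {
  v <- eigenvectorCentrality(ring_net(8, 2))
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  expect_equal(unname(v), rep(v[[1]], 8), tolerance = 1e-9)
  vs <- eigenvectorCentrality(star_net(6))
  expect_gt(vs[[1]], max(vs[-1]))
  expect_error(eigenvectorCentrality(net_from_edges(4, list())),
               "edgeless")
})

test_that("pagerank sums to 1, is uniform on cycles, and handles isolated
           nodes by the uniform-redistribution rule", {
  p <- pageRankCentrality(ring_net(6, 2))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p), rep(1 / 6, 6), tolerance = 1e-10)
  # isolated node + triangle: compare with the 100-step brute iteration
  iso_k3 <- net_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3)))
  got <- pageRankCentrality(iso_k3)
  expect_equal(unname(got), oracle_pagerank(adjacencyMatrix(iso_k3)),
               tolerance = 1e-9)
  # closed form for the dangling node: p = (1-d)/n + d p / n
  d <- 0.85
  expect_equal(unname(got[4]), ((1 - d) / 4) / (1 - d / 4),
               tolerance = 1e-9)
})

test_that("coreness: cliques, stars, and a clique with a pendant", {
  expect_equal(unname(kCoreness(complete_net(5))), rep(4L, 5))
  expect_equal(unname(kCoreness(star_net(6))), rep(1L, 7))
  k4_pendant <- net_from_edges(5, c(utils::combn(1:4, 2, simplify = FALSE),
                                    list(c(4, 5))))
  expect_equal(unname(kCoreness(k4_pendant)), c(3L, 3L, 3L, 3L, 1L))
})

test_that("subgraph centrality: isolated node 1, K2 cosh(1), series oracle", {
  iso <- net_from_edges(3, list(c(2, 3)))
  sc <- subgraphCentrality(iso)
  expect_equal(unname(sc[1]), 1, tolerance = 1e-12)
  expect_equal(unname(sc[2]), cosh(1), tolerance = 1e-10)
  net <- random_network(8, p = 0.45, seed = 5)
  expect_equal(unname(subgraphCentrality(net)),
               oracle_subgraph(adjacencyMatrix(net)), tolerance = 1e-8)
})

test_that("participation and diversity closed forms", {
  # 4 nodes in 2 modules; node 1 has one link in each module
  net <- net_from_edges(4, list(c(1, 2), c(1, 3)))
  part <- new("ModulePartition",
              assignment = setNames(c("A", "A", "B", "B"),
                                    regionLabels(net)),
              source = "a_priori_six")
  p <- participationCoefficient(net, part)
  expect_equal(unname(p[1]), 0.5)     # 1 - 2 (1/2)^2
  expect_equal(unname(p[2]), 0)       # single link inside own module
  dv <- diversityCoefficient(net, part)
  expect_equal(unname(dv[1]), 1)      # even spread over both modules
  expect_equal(unname(dv[2]), 0)
  expect_equal(unname(p[4]), 0)       # isolated
})

test_that("local metrics match brute-force oracles on random graphs", {
  for (seed in 1:25) {
    n <- sample(6:12, 1)
    net <- random_network(n, p = stats::runif(1, 0.25, 0.7),
                          seed = 100 + seed)
    adj <- adjacencyMatrix(net)
    expect_equal(unname(nodeBetweenness(net)), oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(unname(nodeCloseness(net)), oracle_closeness(adj),
                 tolerance = 1e-12)
    expect_equal(unname(kCoreness(net)), oracle_coreness(adj))
    expect_equal(unname(subgraphCentrality(net)), oracle_subgraph(adj),
                 tolerance = 1e-8)
    expect_equal(unname(pageRankCentrality(net)), oracle_pagerank(adj),
                 tolerance = 1e-8)
    connected <- edgeCount(net) > 0 &&
      !characteristicPathLength(net)$fragmented
    if (connected) {
      # eigenvector centrality is compared on connected graphs only:
      # with several components the principal eigenvector is not unique
      ev <- eigenvectorCentrality(net)
      ov <- oracle_eigenvector(adj)
      expect_equal(unname(ev), ov, tolerance = 1e-6)
    }
    mod <- rep(c("A", "B", "C"), length.out = n)
    part <- new("ModulePartition",
                assignment = setNames(mod, regionLabels(net)),
                source = "a_priori_six")
    expect_equal(unname(participationCoefficient(net, part)),
                 oracle_participation(adj, mod), tolerance = 1e-12)
    expect_equal(unname(diversityCoefficient(net, part)),
                 oracle_diversity(adj, mod), tolerance = 1e-12)
  }
})

test_that("centralities are equivariant under node relabelling", {
  net <- random_network(10, p = 0.4, seed = 77)
  adj <- adjacencyMatrix(net)
  set.seed(8)
  for (rep in 1:5) {
    perm <- sample(10)
    padj <- adj[perm, perm]
    pnet <- conngraph:::.new_network(padj, networkDensity(net))
    expect_equal(unname(nodeBetweenness(pnet)),
                 unname(nodeBetweenness(net))[perm], tolerance = 1e-10)
    expect_equal(unname(kCoreness(pnet)),
                 unname(kCoreness(net))[perm])
    expect_equal(unname(pageRankCentrality(pnet)),
                 unname(pageRankCentrality(net))[perm], tolerance = 1e-9)
    expect_equal(unname(subgraphCentrality(pnet)),
                 unname(subgraphCentrality(net))[perm], tolerance = 1e-8)
  }
})

test_that("localMetrics assembles all nine measures with invariants", {
  net <- random_network(12, p = 0.4, seed = 13)
  part <- new("ModulePartition",
              assignment = setNames(rep(c("A", "B", "C", "D"), 3),
                                    regionLabels(net)),
              source = "a_priori_six")
  lm <- localMetrics(net, part)
  expect_equal(nrow(lm), 12)
  expect_equal(sum(lm$pagerank), 1, tolerance = 1e-9)
  expect_equal(sum(lm$eigenvector^2), 1, tolerance = 1e-9)
  expect_true(all(lm$participation >= 0 & lm$participation <= 1 - 1 / 4 + 1e-12))
  expect_true(all(lm$subgraph >= 1 - 1e-12))
  expect_true(all(lm$betweenness >= 0 & lm$betweenness <= 1))
})
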