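test_that("closed forms: complete graphs, stars, rings", {
  k5 <- complete_net(5)
  expect_equal(unname(clusteringCoefficient(k5)$node), rep(1, 5))
  expect_equal(clusteringCoefficient(k5)$mean, 1)
  expect_equal(graphTransitivity(complete_net(4)), 1)
  expect_equal(characteristicPathLength(complete_net(7))$L, 1)
  expect_false(characteristicPathLength(complete_net(7))$fragmented)
  expect_equal(globalEfficiency(complete_net(5)), 1)
  expect_equal(localEfficiency(complete_net(5))$mean, 1)

  s6 <- star_net(6)
  expect_equal(unname(clusteringCoefficient(s6)$node), rep(0, 7))
  expect_equal(localEfficiency(s6)$mean, 0)
  expect_equal(degreeAssortativity(s6), -1)

  c6 <- ring_net(6, 2)
  expect_equal(characteristicPathLength(c6)$L, 1.8)   # (1+1+2+2+3)/5
  expect_equal(globalEfficiency(c6), mean(c(1, 1, 1/2, 1/2, 1/3)))
  # path graph has no triangles
  p4 <- net_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(graphTransitivity(p4), 0)
})

test_that("fragmented graphs use the finite-pair convention and flag it", {
  two_tri <- net_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                    c(4, 5), c(4, 6), c(5, 6)))
  cpl <- characteristicPathLength(two_tri)
  expect_equal(cpl$L, 1)
  expect_true(cpl$fragmented)
  expect_error(characteristicPathLength(net_from_edges(3, list())),
               "edgeless")
  expect_equal(globalEfficiency(net_from_edges(5, list())), 0)
})

test_that("global measures match brute-force oracles on random graphs", {
  for (seed in 1:25) {
    n <- sample(5:12, 1)
    net <- random_network(n, p = stats::runif(1, 0.2, 0.7), seed = seed)
    adj <- adjacencyMatrix(net)
    expect_equal(unname(clusteringCoefficient(net)$node),
                 oracle_clustering(adj), tolerance = 1e-12)
    expect_equal(graphTransitivity(net), oracle_transitivity(adj),
                 tolerance = 1e-12)
    if (edgeCount(net) > 0) {
      o <- oracle_path_length(adj)
      got <- characteristicPathLength(net)
      expect_equal(got$L, o$L, tolerance = 1e-12)
      expect_equal(got$fragmented, o$fragmented)
    }
    expect_equal(globalEfficiency(net), oracle_global_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(unname(localEfficiency(net)$node),
                 oracle_local_efficiency(adj), tolerance = 1e-12)
    if (edgeCount(net) > 0 && stats::var(colSums(adj)) > 0)
      expect_equal(degreeAssortativity(net), oracle_assortativity(adj),
                   tolerance = 1e-12)
  }
})

test_that("regular graphs return NA assortativity with a warning", {
  expect_warning(a <- degreeAssortativity(ring_net(8, 2)), "undefined")
  expect_true(is.na(a))
})

test_that("modularity recovers planted cliques and matches hand-computed Q", {
  # two K5 cliques joined by one edge; for that split
  # Q = sum_c (e_c/m - (d_c/2m)^2) = 2 * (10/21 - (21/42)^2)
  edges <- c(utils::combn(1:5, 2, simplify = FALSE),
             utils::combn(6:10, 2, simplify = FALSE), list(c(5, 6)))
  net <- net_from_edges(10, edges)
  res <- modularityPartition(net, seed = 1)
  mem <- moduleAssignment(res$partition)
  expect_length(unique(mem), 2)
  expect_equal(unname(mem[1:5]), rep(mem[[1]], 5))
  expect_equal(unname(mem[6:10]), rep(mem[[6]], 5))
  q_hand <- 2 * (10 / 21 - (21 / 42)^2)
  expect_equal(res$Q, q_hand, tolerance = 1e-12)
  # complete graph: no split improves on the trivial partition
  expect_lte(modularityPartition(complete_net(6), seed = 2)$Q, 1e-12)
})

test_that("modularity is reproducible across calls with the same seed", {
  net <- random_network(40, p = 0.15, seed = 12)
  r1 <- modularityPartition(net, seed = 5)
  r2 <- modularityPartition(net, seed = 5)
  expect_identical(r1$Q, r2$Q)
  expect_identical(moduleAssignment(r1$partition),
                   moduleAssignment(r2$partition))
})

test_that("sigma is 1 against an ensemble of copies and > 1 for modular nets", {
  net <- random_network(20, p = 0.3, seed = 9)
  self_ens <- new("NullEnsemble", source = net,
                  members = replicate(5, net), nNulls = 5L,
                  rewiresPerEdge = 0L, seed = 1L)
  expect_equal(smallWorldSigma(net, self_ens), 1)
  # clustered modular graph vs degree-preserving nulls
  cfg <- synthConfig(nSubjects = 1, nRegions = 48, nTimepoints = 400,
                     moduleSizes = rep(8L, 6), withinCoupling = 0.7,
                     betweenCoupling = 0.3, hubCoupling = 0, hubBoost = 0,
                     bridgeCoupling = 0, blockContrast = 0,
                     conditionEffect = 0, timeEffect = 0, seed = 4)
  rec <- generateCohort(cfg)[[1]]
  mod_net <- proportionalThreshold(correlate(rec), 0.12)
  ens <- buildEnsemble(mod_net, nNulls = 10, seed = 2)
  expect_gt(smallWorldSigma(mod_net, ens), 1.3)
})

test_that("a Watts-Strogatz-style rewired lattice is smaller-world than the lattice", {
  lattice <- ring_net(100, 4)
  # rewire a fraction of edges to create shortcuts
  set.seed(31)
  adj <- adjacencyMatrix(lattice)
  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  sel <- sample(nrow(edges), 20)
  for (i in sel) {
    a <- edges[i, 1]
    b <- sample(setdiff(1:100, c(a, which(adj[a, ] == 1L))), 1)
    adj[edges[i, 1], edges[i, 2]] <- adj[edges[i, 2], edges[i, 1]] <- 0L
    adj[a, b] <- adj[b, a] <- 1L
  }
  ws <- conngraph:::.new_network(adj, 0.08)
  sig_lattice <- smallWorldSigma(lattice,
                                 buildEnsemble(lattice, 10, seed = 3))
  sig_ws <- smallWorldSigma(ws, buildEnsemble(ws, 10, seed = 3))
  expect_gt(sig_ws, sig_lattice)
})

test_that("L and efficiency are inversely ordered across a density sweep", {
  set.seed(17)
  cm <- correlate(matrix(rnorm(300 * 40), 300, 40))
  nets <- densitySweep(cm, 0.10, 0.30, 0.05)
  Ls <- vapply(nets, function(n) characteristicPathLength(n)$L, numeric(1))
  Es <- vapply(nets, globalEfficiency, numeric(1))
  expect_true(all(diff(Ls) <= 1e-12))
  expect_true(all(diff(Es) >= -1e-12))
})

test_that("globalMetrics returns a coherent one-row panel", {
  net <- random_network(25, p = 0.3, seed = 21)
  gm <- globalMetrics(net, nNulls = 5, seed = 2)
  expect_equal(nrow(gm), 1)
  expect_true(all(c("clustering", "transitivity", "modularity",
                    "path_length", "global_efficiency",
                    "local_efficiency", "small_world", "assortativity",
                    "fragmented") %in% names(gm)))
  expect_gte(gm$clustering, 0); expect_lte(gm$clustering, 1)
  expect_gte(gm$global_efficiency, 0); expect_lte(gm$global_efficiency, 1)
  expect_gte(gm$path_length, 1)
})
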