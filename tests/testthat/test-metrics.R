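# Node and graph topology statistics against brute-force oracles.

test_that("importance centrality and clustering follow the printed formulas", {
  # star S4: centre has d = 4, a = 0 -> c = d(d-1)+1 = 13, phi = 0
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("n", 1:5)
  nm <- nodeMetrics(MicrobialNetwork(star))
  centre <- nm[nm$node == "n1", ]
  expect_identical(centre$degree, 4L)
  expect_identical(centre$a, 0L)
  expect_equal(centre$importance, 13)
  expect_equal(centre$phi, 0)
  # all leaf pairs route through the centre: betweenness = C(4,2) = 6
  expect_equal(centre$betweenness, 6)
  # leaves: d = 1, a = 0 -> c = 1, phi undefined
  leaf <- nm[nm$node == "n2", ]
  expect_equal(leaf$importance, 1)
  expect_true(is.na(leaf$phi))

  # d = 3 with mutually unconnected neighbours: c = 7, phi = 0
  g <- igraph::graph_from_edgelist(
    cbind("h", c("x", "y", "z")),
    directed = FALSE
  )
  nmh <- nodeMetrics(MicrobialNetwork(g))
  expect_equal(nmh$importance[nmh$node == "h"], 7)
  expect_equal(nmh$phi[nmh$node == "h"], 0)

  # d = 4 with a = 2: c = 13/5, phi = 1/3
  edges <- rbind(
    cbind("v", c("a", "b", "c", "d")),
    c("a", "b"), c("c", "d")
  )
  g2 <- igraph::graph_from_edgelist(edges, directed = FALSE)
  nm2 <- nodeMetrics(MicrobialNetwork(g2))
  expect_equal(nm2$importance[nm2$node == "v"], 2.6)
  expect_equal(nm2$phi[nm2$node == "v"], 1 / 3)

  # isolated node: the printed formula collapses to c = 1
  g3 <- igraph::add_vertices(g2, 1, name = "iso")
  nm3 <- nodeMetrics(MicrobialNetwork(g3))
  expect_equal(nm3$importance[nm3$node == "iso"], 1)
  expect_identical(nm3$degree[nm3$node == "iso"], 0L)
})

test_that("two bridged K4 cliques give the known modularity and APL", {
  net <- generateToyGraph("two_cliques_bridged", list(k = 4))
  gm <- graphMetrics(net)
  # clique partition: Q = 2 (6/13 - (13/26)^2) = 11/26
  expect_equal(gm$modularityQ, 11 / 26, tolerance = 1e-9)
  expect_identical(length(unique(gm$partition)), 2L)
  # brute-force Q of the recovered partition agrees with igraph's value
  adj <- netAdjacency(net)
  expect_equal(gm$modularityQ, bruteModularity(adj, gm$partition),
    tolerance = 1e-12
  )
  expect_equal(gm$apl, bruteApl(adj), tolerance = 1e-12)
})

test_that("a graph with exact power-law degree frequencies has index 1", {
  # degrees 1, 2, 4 with counts 16, 4, 1: P(d) is proportional to d^-2,
  # so the log-log points are collinear and r-squared is exactly 1
  edges <- rbind(
    cbind("hub", paste0("m", 1:4)),
    cbind(paste0("m", 1:4), paste0("l", 1:4)),
    cbind(paste0("p", 1:6), paste0("q", 1:6))
  )
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_equal(igraph::vcount(g), 21L)
  tab <- table(igraph::degree(g))
  expect_equal(as.integer(tab[c("1", "2", "4")]), c(16L, 4L, 1L))
  gm <- graphMetrics(MicrobialNetwork(g))
  expect_equal(gm$scaleFreeR2, 1, tolerance = 1e-9)
  expect_equal(gm$gammaHat, 2, tolerance = 1e-9)
})

test_that("scale-free index is undefined below 3 distinct degrees", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("n", 1:6)
  gm <- graphMetrics(MicrobialNetwork(ring))
  expect_true(is.na(gm$scaleFreeR2))
  expect_match(gm$notes[["scale_free"]], "distinct positive degrees")
})

test_that("average path length matches enumeration on P3", {
  p3 <- igraph::make_ring(3, circular = FALSE)
  igraph::V(p3)$name <- paste0("n", 1:3)
  expect_equal(graphMetrics(MicrobialNetwork(p3))$apl, 4 / 3)
})

test_that("node metrics match brute force on random small graphs", {
  # spot sample here; the full 200-graph sweep runs in the acceptance suite
  set.seed(101)
  for (k in 1:40) {
    n <- sample(4:7, 1)
    m <- sample(seq_len(choose(n, 2)), 1)
    net <- randomNetwork(n, m, seed = 1000 + k)
    adj <- netAdjacency(net)
    nm <- nodeMetrics(net)
    oracle <- bruteNodeStats(adj)
    expect_identical(nm$degree, oracle$degree)
    expect_identical(nm$a, oracle$a)
    expect_equal(nm$phi, oracle$phi)
    expect_equal(nm$importance, oracle$importance)
    expect_equal(nm$betweenness, bruteBetweenness(adj), tolerance = 1e-9)
    if (igraph::ecount(networkGraph(net)) > 0) {
      expect_equal(graphMetrics(net)$apl, bruteApl(adj), tolerance = 1e-12)
    }
    # importance is decreasing in a at fixed d and increasing in d at fixed a
    with(nm, {
      for (i in seq_len(nrow(nm))) {
        for (j in seq_len(nrow(nm))) {
          if (degree[i] == degree[j] && a[i] < a[j]) {
            expect_gt(importance[i], importance[j])
          }
          # d = 0 and d = 1 tie at c = 1 (the formula's quirk), so the
          # strict-increase check needs the larger degree to be >= 2
          if (a[i] == a[j] && degree[i] > degree[j] && degree[i] >= 2) {
            expect_gt(importance[i], importance[j])
          }
        }
      }
    })
  }
})

test_that("modularity of the trivial single-community partition is zero", {
  net <- generateToyGraph("two_cliques_bridged", list(k = 5))
  g <- networkGraph(net)
  single <- rep(1L, igraph::vcount(g))
  expect_identical(igraph::modularity(g, single), 0)
  # walktrap's cut does at least as well as the trivial partition
  expect_gte(graphMetrics(net)$modularityQ, 0)
  # any partition stays within [-0.5, 1]
  set.seed(7)
  for (k in 1:20) {
    memb <- sample(1:3, igraph::vcount(g), replace = TRUE)
    Q <- igraph::modularity(g, memb)
    expect_gte(Q, -0.5)
    expect_lte(Q, 1)
    expect_equal(Q, bruteModularity(netAdjacency(net), memb),
      tolerance = 1e-12
    )
  }
})

test_that("null-model test bounds and degenerate cases behave", {
  # the complete graph: every G(n, m) null IS the same graph, so the
  # one-sided p hits the estimator bound (1 + k)/(1 + n) = 1
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("n", 1:5)
  nt <- nullModelTest(MicrobialNetwork(k5), "modularity", nRandom = 1,
    seed = 1)
  expect_equal(nt$p, 1)
  expect_error(
    nullModelTest(
      MicrobialNetwork(igraph::make_full_graph(4,
        directed = FALSE
      )) # fine
      , "modularity",
      nRandom = 0
    ),
    "nRandom"
  )
})

test_that("planted two-clique structure is significant against G(n, m)", {
  net <- generateToyGraph("two_cliques_bridged", list(k = 6))
  nt <- nullModelTest(net, "modularity", nRandom = 199, seed = 11)
  expect_lte(nt$p, 0.01)
  expect_gt(nt$observed, nt$nullMean)
})

test_that("class ablation reports deltas and handles edge cases", {
  # two bacteria K4 cliques joined only through one phage
  edges <- rbind(
    t(combn(paste0("a", 1:4), 2)),
    t(combn(paste0("b", 1:4), 2)),
    c("v", "a1"), c("v", "b1")
  )
  nodes <- data.frame(
    name = c(paste0("a", 1:4), paste0("b", 1:4), "v"),
    class = c(rep("bacteria", 8), "phage")
  )
  net <- buildNetwork(as.data.frame(edges, stringsAsFactors = FALSE) |>
    setNames(c("source", "target")), nodes)
  rep_ <- ablateClass(net, "all_viruses")
  dQ <- rep_$delta[rep_$metric == "modularity"]
  expect_gt(dQ, 0) # bridging virus removed: modularity rises
  # removing a class with no members changes nothing
  rep0 <- ablateClass(net, "eukaryotic_virus")
  expect_equal(rep0$before, rep0$after, tolerance = 1e-12)
  # removal that empties the graph errors
  allv <- buildNetwork(
    data.frame(source = "v1", target = "v2"),
    data.frame(name = c("v1", "v2"), class = "phage")
  )
  expect_error(ablateClass(allv, "phage"), "empty")
})

test_that("isolated virus nodes do not alter APL on removal", {
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- paste0("b", 1:5)
  igraph::V(g)$class <- "bacteria"
  g <- igraph::add_vertices(g, 2, name = c("v1", "v2"), class = "phage")
  net <- MicrobialNetwork(g)
  rep_ <- ablateClass(net, "phage")
  expect_equal(rep_$delta[rep_$metric == "apl"], 0)
})
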