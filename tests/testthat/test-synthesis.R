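# Family-level mapping, pan/core construction, key-virus selection.

genusNet <- function(edges, group = "net") {
  nodes <- data.frame(
    name = c("g1", "g2", "g3", "g4", "g5"),
    class = c("bacteria", "bacteria", "bacteria", "phage", "phage"),
    genus = c("g1", "g2", "g3", "g4", "g5"),
    family = c("F1", "F1", "F2", "F3", "F3"),
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", NA, NA)
  )
  buildNetwork(edges, nodes, group = group)
}

test_that("family mapping merges same-sign links and removes conflicts", {
  # two genus edges onto the same family pair, both positive -> one edge
  net <- genusNet(data.frame(
    source = c("g1", "g2"), target = c("g3", "g3"),
    sign = c("positive", "positive")
  ))
  fam <- toFamilyLevel(net)
  e <- networkEdges(fam)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$source, e$target), c("F1", "F2"))
  expect_identical(e$sign, "positive")

  # conflicting signs on the same family pair -> pair dropped entirely
  net2 <- genusNet(data.frame(
    source = c("g1", "g2"), target = c("g3", "g3"),
    sign = c("positive", "negative")
  ))
  expect_identical(nrow(networkEdges(toFamilyLevel(net2))), 0L)

  # within-family genus edge -> self-loop, dropped
  net3 <- genusNet(data.frame(
    source = "g1", target = "g2", sign = "positive"
  ))
  expect_identical(nrow(networkEdges(toFamilyLevel(net3))), 0L)
})

test_that("family mapping is idempotent and annotates family nodes", {
  net <- genusNet(data.frame(
    source = c("g1", "g3", "g4"), target = c("g3", "g4", "g1"),
    sign = c("positive", "negative", "positive")
  ))
  once <- toFamilyLevel(net)
  twice <- toFamilyLevel(once)
  expect_identical(
    networkEdges(once)[order(networkEdges(once)$source), ],
    networkEdges(twice)[order(networkEdges(twice)$source), ]
  )
  nodes <- networkNodes(once)
  expect_identical(nodes$class[nodes$name == "F3"], "phage")
  expect_identical(nodes$class[nodes$name == "F1"], "bacteria")
})

test_that("nodes without family annotation fall back with a warning", {
  nodes <- data.frame(
    name = c("x", "y"), class = "bacteria", genus = c("x", "y"),
    family = c(NA, "F9"), phylum = NA
  )
  net <- buildNetwork(
    data.frame(source = "x", target = "y", sign = "positive"), nodes
  )
  expect_warning(fam <- toFamilyLevel(net), "unclassified_family")
  expect_true("unclassified_family" %in% networkNodes(fam)$name)
})

test_that("pan and core networks follow the recurrence and conflict rules", {
  mk <- function(edges, tag) {
    nodes <- data.frame(
      name = c("F1", "F2", "F3", "F4"), class = "bacteria",
      genus = NA, family = c("F1", "F2", "F3", "F4"), phylum = "Firmicutes"
    )
    nodes <- nodes[nodes$name %in% unique(c(edges$source, edges$target)), ]
    buildNetwork(edges, nodes, group = tag)
  }
  e <- function(s, t, sgn) data.frame(source = s, target = t, sign = sgn)
  # F1-F2 positive in networks 1-4 (core at >= 4); F1-F3 positive in 1-3
  # only (pan, not core); F2-F3 positive in 1-3 but negative in 4-5
  # (sign conflict -> removed everywhere)
  nets <- list(
    mk(rbind(e("F1", "F2", "positive"), e("F1", "F3", "positive"),
      e("F2", "F3", "positive")), "n1"),
    mk(rbind(e("F1", "F2", "positive"), e("F1", "F3", "positive"),
      e("F2", "F3", "positive")), "n2"),
    mk(rbind(e("F1", "F2", "positive"), e("F1", "F3", "positive"),
      e("F2", "F3", "positive")), "n3"),
    mk(rbind(e("F1", "F2", "positive"), e("F2", "F3", "negative")), "n4"),
    mk(e("F2", "F3", "negative"), "n5")
  )
  pc <- panCore(nets, coreMin = 4)
  pan <- networkEdges(pc$pan)
  core <- networkEdges(pc$core)
  pank <- edgeKeyTest(pan$source, pan$target)
  corek <- edgeKeyTest(core$source, core$target)
  expect_true(edgeKeyTest("F1", "F2") %in% corek) # 4 of 5 -> core
  expect_true(edgeKeyTest("F1", "F3") %in% pank) # 3 of 5 -> pan only
  expect_false(edgeKeyTest("F1", "F3") %in% corek)
  expect_false(edgeKeyTest("F2", "F3") %in% pank) # conflicted -> removed
  expect_false(edgeKeyTest("F2", "F3") %in% corek)
  # occurrence counts recorded
  expect_identical(pan$occurrence[pank == edgeKeyTest("F1", "F2")], 4L)
  # keepConflicts retains the pair, tagged
  pc2 <- panCore(nets, coreMin = 4, keepConflicts = TRUE)
  pan2 <- networkEdges(pc2$pan)
  k2 <- edgeKeyTest(pan2$source, pan2$target)
  expect_true(edgeKeyTest("F2", "F3") %in% k2)
  expect_true(pan2$sign_conflict[k2 == edgeKeyTest("F2", "F3")])
})

test_that("core is always an edge subset of pan", {
  set.seed(33)
  for (rep in 1:10) {
    nets <- lapply(1:5, function(i) {
      net <- randomNetwork(6, sample(4:10, 1), seed = 100 * rep + i)
      g <- networkGraph(net)
      igraph::V(g)$family <- paste0("F", seq_len(igraph::vcount(g)))
      igraph::E(g)$sign <- sample(c("positive", "negative"),
        igraph::ecount(g),
        replace = TRUE
      )
      MicrobialNetwork(g, group = paste0("g", i))
    })
    pc <- panCore(nets, coreMin = 3)
    pank <- with(networkEdges(pc$pan), edgeKeyTest(source, target))
    corek <- with(networkEdges(pc$core), edgeKeyTest(source, target))
    expect_true(all(corek %in% pank))
  }
})

test_that("ring-with-shortcut key virus lowers the bacterial APL from 16/7", {
  net <- generateToyGraph("ring_with_shortcut", list(n = 8))
  kv <- keyVirusSelection(net)
  expect_equal(baselineApl(kv), 16 / 7, tolerance = 1e-12)
  adds <- virusAdditions(kv)
  expect_identical(adds$node[1], "v1")
  expect_lt(adds$aplAfter[1], 16 / 7)
  expect_equal(adds$aplAfter[1], 31 / 14, tolerance = 1e-12)
  expect_identical(selectedViruses(kv), "v1")
})

test_that("a pendant virus leaves the bacterial APL unchanged", {
  g <- igraph::make_ring(6)
  igraph::V(g)$name <- paste0("b", 1:6)
  igraph::V(g)$class <- "bacteria"
  g <- igraph::add_vertices(g, 1, name = "v1", class = "eukaryotic_virus")
  g <- igraph::add_edges(g, c(7, 1))
  kv <- keyVirusSelection(MicrobialNetwork(g))
  expect_equal(virusAdditions(kv)$aplAfter[1], baselineApl(kv))
  # no improvement anywhere on the trajectory: nothing selected
  expect_identical(selectedViruses(kv), character())
})

test_that("betweenness-ordered trajectory attains the exhaustive minimum", {
  # on connected bacterial backbones, adding viruses never lengthens paths,
  # so the trajectory minimum must equal the best over all virus subsets;
  # checked by exhaustive enumeration
  set.seed(55)
  for (rep in 1:12) {
    nB <- sample(5:10, 1)
    nV <- sample(1:4, 1)
    base <- igraph::sample_gnm(nB, min(choose(nB, 2), nB + 3))
    while (!igraph::is_connected(base)) {
      base <- igraph::sample_gnm(nB, min(choose(nB, 2), nB + 3))
    }
    igraph::V(base)$name <- paste0("b", seq_len(nB))
    igraph::V(base)$class <- "bacteria"
    g <- base
    for (v in seq_len(nV)) {
      g <- igraph::add_vertices(g, 1,
        name = paste0("v", v),
        class = "phage"
      )
      nb <- sample(seq_len(nB), sample(2:3, 1))
      g <- igraph::add_edges(g, as.vector(rbind(nB + v, nb)))
    }
    net <- MicrobialNetwork(g)
    kv <- keyVirusSelection(net)
    trajMin <- min(c(baselineApl(kv), virusAdditions(kv)$aplAfter))
    # exhaustive oracle over all 2^nV virus subsets
    bact <- paste0("b", seq_len(nB))
    best <- Inf
    for (mask in 0:(2^nV - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nV) - 1)) > 0)
      keep <- c(bact, if (length(sel)) paste0("v", sel))
      sub <- igraph::induced_subgraph(g, match(keep, igraph::V(g)$name))
      dm <- igraph::distances(sub,
        v = match(bact, igraph::V(sub)$name),
        to = match(bact, igraph::V(sub)$name), weights = NA
      )
      vals <- dm[upper.tri(dm)]
      best <- min(best, mean(vals[is.finite(vals)]))
    }
    expect_equal(trajMin, best, tolerance = 1e-12)
  }
})

test_that("key-virus APL trajectory is invariant to node relabelling", {
  net <- generateToyGraph("ring_with_shortcut", list(n = 10))
  g <- networkGraph(net)
  g2 <- g
  igraph::V(g2)$name <- rev(igraph::V(g2)$name) # relabel, same topology
  kv1 <- keyVirusSelection(net)
  kv2 <- keyVirusSelection(MicrobialNetwork(g2))
  expect_equal(baselineApl(kv1), baselineApl(kv2))
  expect_equal(virusAdditions(kv1)$aplAfter, virusAdditions(kv2)$aplAfter)
})

test_that("virus-free networks give a baseline-only report", {
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- paste0("b", 1:5)
  igraph::V(g)$class <- "bacteria"
  kv <- keyVirusSelection(MicrobialNetwork(g))
  expect_identical(nrow(virusAdditions(kv)), 0L)
  expect_identical(selectedViruses(kv), character())
  expect_equal(baselineApl(kv), 1.5)
})
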