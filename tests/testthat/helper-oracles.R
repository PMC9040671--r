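# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's own code paths (and igraph's metric
# functions) so they can serve as cross-checks.

# All-pairs shortest-path distances by Floyd-Warshall on an adjacency matrix.
bruteDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Betweenness by exhaustive shortest-path enumeration (each unordered pair
# once, split equally across its shortest paths).
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  if (n < 3) {
    return(btw)
  }
  dist <- bruteDistances(adj)
  allShortestPaths <- function(s, t, len) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        if (length(path) == len + 1) res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      if (length(path) > len) {
        return(invisible())
      }
      for (u in which(adj[v, ] > 0)) {
        if (!(u %in% path)) rec(c(path, u))
      }
    }
    rec(s)
    res
  }
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(dist[s, t]) || dist[s, t] < 2) next
      paths <- allShortestPaths(s, t, dist[s, t])
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
  }
  btw
}

# Average path length over reachable unordered pairs.
bruteApl <- function(adj) {
  d <- bruteDistances(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (!length(vals)) {
    return(NA_real_)
  }
  mean(vals)
}

# Degree, neighbour-edge count, clustering coefficient and importance
# centrality by direct neighbour-edge counting.
bruteNodeStats <- function(adj) {
  n <- nrow(adj)
  out <- data.frame(
    degree = integer(n), a = integer(n), phi = numeric(n),
    importance = numeric(n)
  )
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    d <- length(nb)
    a <- if (d >= 2) sum(adj[nb, nb]) / 2 else 0
    out$degree[v] <- d
    out$a[v] <- as.integer(a)
    out$phi[v] <- if (d >= 2) 2 * a / (d * (d - 1)) else NA_real_
    out$importance[v] <- (d * (d - 1) + 1) / (2 * a + 1)
  }
  out
}

# Newman modularity of a given partition, straight from the definition
# Q = sum_c (e_c / m - (d_c / 2m)^2).
bruteModularity <- function(adj, membership) {
  m <- sum(adj) / 2
  stopifnot(m > 0)
  Q <- 0
  for (com in unique(membership)) {
    idx <- which(membership == com)
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(adj[idx, ])
    Q <- Q + e_c / m - (d_c / (2 * m))^2
  }
  Q
}

# Textbook Benjamini-Hochberg step-up q-values.
bhTextbook <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in seq(m, 1)) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# Exact two-sided permutation-enrichment p-value: n4 ~ Hypergeom drawing n2
# of the n1 links when m_ph of them belong to the phylum; doubled smaller
# tail, capped at 1.
exactTwoSidedHyper <- function(n1, n2, m_ph, n3) {
  upper <- sum(stats::dhyper(n3:min(n2, m_ph), m_ph, n1 - m_ph, n2))
  lower <- sum(stats::dhyper(0:n3, m_ph, n1 - m_ph, n2))
  min(1, 2 * min(upper, lower))
}

# Random annotated simple graph as a MicrobialNetwork (G(n, m) draw).
randomNetwork <- function(n, m, seed, classes = "bacteria") {
  generateToyGraph("random_gnm", list(n = n, m = m, classes = classes),
    seed = seed
  )
}

# Adjacency matrix of a MicrobialNetwork in vertex order.
netAdjacency <- function(net) {
  igraph::as_adjacency_matrix(networkGraph(net), sparse = FALSE)
}

# Equicorrelated-module cohort builders used by the differential tests.
# D taxa, a module of `moduleSize` bacteria planted at correlation `r` in
# the arms selected by `where`.
moduleCohortSpec <- function(D = 30L, moduleSize = 16L, r = 0.8,
                             where = c("case", "both"), n = 200L,
                             depth = 1e5, seed = 1L) {
  where <- match.arg(where)
  ts <- makeTaxaSpec(D)
  nm <- ts@taxa$name
  module <- paste0("B", seq_len(moduleSize))
  planted <- plantedPairs(module, r)
  caseCor <- CorrelationStructure(nm, planted)
  controlCor <- if (where == "both") {
    caseCor
  } else {
    CorrelationStructure(nm)
  }
  CohortSpec(ts,
    controlCor = controlCor, caseCor = caseCor,
    nControl = n, nCase = n, depth = depth,
    differentialPairs = if (where == "case") planted[, 1:2] else NULL,
    seed = seed
  )
}

# Build case/control networks + correlation results for a cohort spec.
cohortNetworks <- function(spec, rMin = 0.4, nShuffles = 100L, seed = 1L) {
  cohort <- generateCohort(spec)
  ann <- featureData(cohort$case)
  resCase <- suppressWarnings(
    shuffledPseudoPvalues(cohort$case, nShuffles, seed = seed)
  )
  resCtrl <- suppressWarnings(
    shuffledPseudoPvalues(cohort$control, nShuffles, seed = seed + 1L)
  )
  netCase <- suppressWarnings(
    thresholdNetwork(resCase, ann, rMin = rMin, group = "case")
  )
  netCtrl <- suppressWarnings(
    thresholdNetwork(resCtrl, ann, rMin = rMin, group = "control")
  )
  list(
    resCase = resCase, resCtrl = resCtrl,
    netCase = netCase, netCtrl = netCtrl, annotations = ann
  )
}

# Hand-built MicrobialNetwork from an edge data.frame and a node data.frame.
buildNetwork <- function(edges, nodes, group = "fixture") {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
    vertices = nodes)
  MicrobialNetwork(g, group = group)
}

# Order-independent undirected edge key for test assertions.
edgeKeyTest <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
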