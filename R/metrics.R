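## Node and graph topology statistics.
##
## Node level: degree d, neighbour-edge count a, clustering coefficient
## phi = 2a / (d(d-1)), importance centrality c = (d(d-1) + 1) / (2a + 1)
## (a clustering-coefficient modification that is large for hubs whose
## neighbourhoods are sparsely interconnected; the formula gives c = 1 for
## isolated nodes since both terms collapse to 1), and unnormalized
## betweenness. Graph level: walktrap modularity Q, the scale-free index
## (r-squared of the log-log degree-frequency regression), and average path
## length over reachable pairs.

#' Per-node topology metrics
#'
#' @param g a [MicrobialNetwork-class] or igraph.
#' @return data.frame with columns `node`, `degree`, `a` (edges among
#'   neighbours), `b` (max possible neighbour edges, d(d-1)/2), `phi`
#'   (clustering coefficient, NA when degree < 2), `importance`
#'   ((d(d-1)+1)/(2a+1)) and `betweenness` (unnormalized, unweighted, each
#'   unordered pair counted once with equal splitting across shortest paths).
#' @export
#' @examples
#' star <- igraph::make_star(5, mode = "undirected")
#' igraph::V(star)$name <- paste0("n", 1:5)
#' nodeMetrics(MicrobialNetwork(star))
nodeMetrics <- function(g) {
  g <- if (is(g, "MicrobialNetwork")) g@graph else g
  stopifnot(igraph::is_simple(g), !igraph::is_directed(g))
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2L) {
      return(0)
    }
    sum(adj[nb, nb]) / 2
  }, numeric(1))
  b <- deg * (deg - 1) / 2
  phi <- ifelse(deg >= 2, 2 * a / (deg * (deg - 1)), NA_real_)
  imp <- (deg * (deg - 1) + 1) / (2 * a + 1)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE,
    weights = NA)
  data.frame(
    node = igraph::V(g)$name, degree = as.integer(deg), a = as.integer(a),
    b = as.integer(b), phi = phi, importance = imp,
    betweenness = as.numeric(btw), stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Walktrap partition robust to isolated vertices (each becomes a singleton
# community); returns a membership vector named by node.
walktrapPartition <- function(g, steps = 4L) {
  deg <- igraph::degree(g)
  memb <- integer(igraph::vcount(g))
  names(memb) <- igraph::V(g)$name
  pos <- which(deg > 0)
  if (length(pos)) {
    sub <- igraph::induced_subgraph(g, pos)
    cw <- igraph::cluster_walktrap(sub, steps = steps)
    memb[pos] <- igraph::membership(cw)
  }
  iso <- which(deg == 0)
  if (length(iso)) {
    memb[iso] <- max(memb) + seq_along(iso)
  }
  memb
}

# Scale-free index: OLS of log P(d) on log d over observed positive degrees.
scaleFreeIndex <- function(deg) {
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3L) {
    return(list(
      r2 = NA_real_, gamma = NA_real_,
      reason = "fewer than 3 distinct positive degrees"
    ))
  }
  d <- as.numeric(names(tab))
  P <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log(P) ~ log(d))
  # summary() warns on an exactly collinear fit; r2 = 1 is a valid outcome
  list(
    r2 = suppressWarnings(summary(fit)$r.squared),
    gamma = -unname(stats::coef(fit)[2L]),
    reason = NA_character_
  )
}

#' Graph-level topology metrics
#'
#' Community structure by random-walk (walktrap) agglomeration with the
#' final cut maximizing Newman modularity Q; the scale-free index as the
#' r-squared of the ordinary least-squares fit of log degree-frequency on
#' log degree over observed positive degrees (natural logs, no binning);
#' and the average path length over reachable node pairs.
#'
#' @param g a [MicrobialNetwork-class] or igraph with >= 2 nodes.
#' @param walktrapSteps random-walk length (default 4).
#' @return list with `modularityQ`, `partition` (named membership vector),
#'   `scaleFreeR2`, `gammaHat`, `apl` and `notes` (reasons for undefined
#'   metrics, plus the reachable-pairs APL convention).
#' @export
graphMetrics <- function(g, walktrapSteps = 4L) {
  g <- if (is(g, "MicrobialNetwork")) g@graph else g
  stopifnot(igraph::vcount(g) >= 2L)
  notes <- c(apl = "mean over reachable (same-component) node pairs")
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
    return(list(
      modularityQ = NA_real_, partition = memb, scaleFreeR2 = NA_real_,
      gammaHat = NA_real_, apl = NA_real_,
      notes = c(notes, modularity = "graph has no edges")
    ))
  }
  memb <- walktrapPartition(g, steps = walktrapSteps)
  Q <- igraph::modularity(g, memb)
  sf <- scaleFreeIndex(igraph::degree(g))
  if (!is.na(sf$reason)) notes <- c(notes, scale_free = sf$reason)
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  list(
    modularityQ = Q, partition = memb, scaleFreeR2 = sf$r2,
    gammaHat = sf$gamma, apl = apl, notes = notes
  )
}

# Metric extractors used by the null-model machinery.
metricValue <- function(g, metric, walktrapSteps = 4L) {
  switch(metric,
    modularity = igraph::modularity(g, walktrapPartition(g, walktrapSteps)),
    scale_free = scaleFreeIndex(igraph::degree(g))$r2,
    apl = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  )
}

#' Null-model significance test for a graph statistic
#'
#' Compares the observed modularity, scale-free index or average path length
#' with its distribution over random simple graphs drawn uniformly with the
#' same node and edge counts (G(n, m)). Modularity and scale-free index use
#' the upper tail (more structured than random); APL uses the lower tail
#' (shorter paths than random). Empirical p-values use the add-one
#' estimator.
#'
#' @param g a [MicrobialNetwork-class] or igraph.
#' @param metric `"modularity"`, `"scale_free"` or `"apl"`.
#' @param nRandom number of null graphs (default 1000).
#' @param seed integer seed.
#' @param walktrapSteps walk length for the modularity partition.
#' @return list with `p`, `observed`, `nullMean`, `nullSd`, `nRandom`,
#'   `metric`.
#' @export
nullModelTest <- function(g, metric = c("modularity", "scale_free", "apl"),
                          nRandom = 1000L, seed = 1L, walktrapSteps = 4L) {
  metric <- match.arg(metric)
  g <- if (is(g, "MicrobialNetwork")) g@graph else g
  stopifnot(nRandom >= 1L)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m > choose(n, 2L)) {
    stop("edge count exceeds C(n, 2); not a simple graph", call. = FALSE)
  }
  obs <- metricValue(g, metric, walktrapSteps)
  nulls <- withSeed(seed, {
    vapply(seq_len(nRandom), function(k) {
      metricValue(igraph::sample_gnm(n, m), metric, walktrapSteps)
    }, numeric(1))
  })
  ok <- !is.na(nulls)
  k <- if (metric == "apl") {
    sum(nulls[ok] <= obs)
  } else {
    sum(nulls[ok] >= obs)
  }
  list(
    p = (1 + k) / (1 + sum(ok)), observed = obs,
    nullMean = mean(nulls, na.rm = TRUE), nullSd = stats::sd(nulls[ok]),
    nRandom = as.integer(nRandom), metric = metric
  )
}

#' Recompute graph metrics after removing a node class
#'
#' Removes all nodes of the requested viral class (or both) and reports
#' modularity, scale-free index and APL before and after, with deltas.
#'
#' @param g a [MicrobialNetwork-class].
#' @param classToRemove `"phage"`, `"eukaryotic_virus"` or `"all_viruses"`.
#' @param walktrapSteps walk length for the modularity partition.
#' @return data.frame with columns `metric`, `before`, `after`, `delta`.
#' @export
ablateClass <- function(g, classToRemove = c(
                          "phage", "eukaryotic_virus",
                          "all_viruses"
                        ), walktrapSteps = 4L) {
  classToRemove <- match.arg(classToRemove)
  stopifnot(is(g, "MicrobialNetwork"))
  graph <- g@graph
  classes <- igraph::V(graph)$class
  drop <- if (classToRemove == "all_viruses") {
    classes %in% .VIRUS_CLASSES
  } else {
    classes == classToRemove
  }
  if (all(drop)) stop("removal would empty the graph", call. = FALSE)
  sub <- igraph::induced_subgraph(graph, which(!drop))
  before <- graphMetrics(graph, walktrapSteps)
  after <- graphMetrics(sub, walktrapSteps)
  data.frame(
    metric = c("modularity", "scale_free", "apl"),
    before = c(before$modularityQ, before$scaleFreeR2, before$apl),
    after = c(after$modularityQ, after$scaleFreeR2, after$apl),
    delta = c(
      after$modularityQ - before$modularityQ,
      after$scaleFreeR2 - before$scaleFreeR2,
      after$apl - before$apl
    ),
    stringsAsFactors = FALSE
  )
}
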