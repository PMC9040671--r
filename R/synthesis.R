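## Family-level mapping, pan/core networks, key-virus selection.

#' Collapse a genus-level network to the family level
#'
#' Nodes map to their family annotation (missing families become
#' `"unclassified_family"` with a warning). Parallel genus links with the
#' same family endpoints and the same interaction sign merge into one family
#' link; endpoint pairs carrying both signs are removed entirely;
#' within-family links (self-loops after mapping) are dropped. Idempotent:
#' family nodes map to themselves.
#'
#' @param g a [MicrobialNetwork-class].
#' @return A family-level [MicrobialNetwork-class] (edges keep only `sign`).
#' @export
toFamilyLevel <- function(g) {
  stopifnot(is(g, "MicrobialNetwork"))
  graph <- g@graph
  fam <- igraph::V(graph)$family
  miss <- is.na(fam) | fam == ""
  if (any(miss)) {
    warning(sum(miss), " node(s) lack a family annotation; assigned to",
      " 'unclassified_family'",
      call. = FALSE
    )
    fam[miss] <- "unclassified_family"
  }
  nodes <- data.frame(
    name = fam, class = igraph::V(graph)$class,
    phylum = igraph::V(graph)$phylum, stringsAsFactors = FALSE
  )
  # family-level node attributes: majority class/phylum, ties by first
  pick <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(NA_character_)
    }
    names(sort(table(x), decreasing = TRUE))[1L]
  }
  fam_names <- sort(unique(fam))
  vdf <- data.frame(
    name = fam_names,
    class = vapply(fam_names, function(f) {
      pc <- pick(nodes$class[nodes$name == f])
      if (is.na(pc)) "unclassified" else pc
    }, character(1)),
    genus = NA_character_,
    family = fam_names,
    phylum = vapply(fam_names, function(f) pick(nodes$phylum[nodes$name == f]),
      character(1)),
    stringsAsFactors = FALSE
  )
  et <- edgeTable(graph)
  if (nrow(et)) {
    fs <- fam[match(et$source, igraph::V(graph)$name)]
    ft <- fam[match(et$target, igraph::V(graph)$name)]
    keep <- fs != ft # drop within-family self-loops
    et <- data.frame(
      source = pmin(fs, ft)[keep], target = pmax(fs, ft)[keep],
      sign = et$sign[keep], stringsAsFactors = FALSE
    )
    if (nrow(et)) {
      key <- paste(et$source, et$target, sep = "\r")
      nsign <- tapply(et$sign, key, function(s) length(unique(s)))
      et <- et[!duplicated(key), , drop = FALSE]
      et <- et[nsign[paste(et$source, et$target, sep = "\r")] == 1L, ,
        drop = FALSE
      ]
    }
  } else {
    et <- data.frame(
      source = character(), target = character(), sign = character(),
      stringsAsFactors = FALSE
    )
  }
  gg <- igraph::graph_from_data_frame(et, directed = FALSE, vertices = vdf)
  MicrobialNetwork(gg, group = paste0(g@group, "_family"))
}

#' Pan- (pooled) and core- (shared) networks across groups
#'
#' Maps every input network to the family level (a no-op if already mapped),
#' then pools links: the pan-network is the union of family links whose
#' interaction sign is consistent across all groups carrying them
#' (sign-conflicted endpoint pairs are removed, extending the within-network
#' merge rule across groups; set `keepConflicts = TRUE` to retain them
#' tagged with `sign_conflict`); the core-network keeps links present with
#' the same sign in at least `coreMin` networks. Edges carry an
#' `occurrence` count.
#'
#' @param networks named list of [MicrobialNetwork-class] objects (>= 2).
#' @param coreMin minimum number of networks a core link must appear in
#'   (default 4).
#' @param keepConflicts keep sign-conflicted pan links, tagged (default
#'   FALSE: removed).
#' @return list with `pan` and `core` [MicrobialNetwork-class] objects.
#' @export
panCore <- function(networks, coreMin = 4L, keepConflicts = FALSE) {
  stopifnot(length(networks) >= 2L, coreMin <= length(networks))
  fams <- lapply(networks, toFamilyLevel)
  ets <- lapply(fams, function(f) edgeTable(f@graph))
  all_edges <- do.call(rbind, lapply(seq_along(ets), function(i) {
    e <- ets[[i]]
    if (nrow(e)) e$group_index <- i
    e
  }))
  nodes <- do.call(rbind, lapply(fams, function(f) nodeTable(f@graph)))
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  emptyNet <- function(tag) {
    MicrobialNetwork(igraph::make_empty_graph(0, directed = FALSE),
      group = tag)
  }
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    return(list(pan = emptyNet("pan"), core = emptyNet("core")))
  }
  key <- edgeKey(all_edges$source, all_edges$target)
  agg <- do.call(rbind, lapply(split(all_edges, key), function(e) {
    data.frame(
      source = pmin(e$source[1L], e$target[1L]),
      target = pmax(e$source[1L], e$target[1L]),
      occurrence = length(unique(e$group_index)),
      sign = if (length(unique(e$sign)) == 1L) e$sign[1L] else "conflict",
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  conflicted <- agg$sign == "conflict"
  pan_edges <- if (keepConflicts) {
    agg$sign_conflict <- conflicted
    agg$sign[conflicted] <- "positive" # placeholder sign; flagged
    agg
  } else {
    agg[!conflicted, , drop = FALSE]
  }
  core_edges <- agg[!conflicted & agg$occurrence >= coreMin, , drop = FALSE]
  buildNet <- function(edges, tag) {
    if (nrow(edges) == 0L) {
      return(emptyNet(tag))
    }
    vs <- nodes[nodes$name %in% unique(c(edges$source, edges$target)), ,
      drop = FALSE
    ]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vs)
    MicrobialNetwork(g, group = tag)
  }
  list(pan = buildNet(pan_edges, "pan"), core = buildNet(core_edges, "core"))
}

# APL over bacteria-node pairs only; paths may traverse any node in `graph`.
bacterialApl <- function(graph, bacteria) {
  idx <- match(intersect(bacteria, igraph::V(graph)$name),
    igraph::V(graph)$name)
  if (length(idx) < 2L) {
    return(NA_real_)
  }
  dm <- igraph::distances(graph, v = idx, to = idx, weights = NA)
  vals <- dm[upper.tri(dm)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    return(NA_real_)
  }
  mean(vals)
}

#' Key-virus selection by betweenness-ordered addition
#'
#' Starting from the bacteria-induced subgraph, viral nodes are added one at
#' a time (with all their edges into the current graph) in decreasing order
#' of their betweenness on the full graph (ties broken lexicographically by
#' node name). After each addition the average path length over bacteria
#' pairs is recorded (paths may route through viruses). The selected key
#' viruses are the shortest prefix of the order attaining the global minimum
#' APL along the trajectory; an empty prefix means no virus shortens the
#' bacterial APL.
#'
#' @param g a [MicrobialNetwork-class] with >= 2 bacteria nodes.
#' @return A [KeyVirusReport-class].
#' @export
keyVirusSelection <- function(g) {
  stopifnot(is(g, "MicrobialNetwork"))
  graph <- g@graph
  classes <- igraph::V(graph)$class
  bacteria <- igraph::V(graph)$name[classes == "bacteria"]
  viruses <- igraph::V(graph)$name[classes %in% .VIRUS_CLASSES]
  if (length(bacteria) < 2L) {
    stop("need at least 2 bacteria nodes", call. = FALSE)
  }
  bact_graph <- igraph::induced_subgraph(
    graph, match(bacteria, igraph::V(graph)$name)
  )
  baseline <- bacterialApl(bact_graph, bacteria)
  notes <- character()
  if (!igraph::is_connected(bact_graph)) {
    notes <- c(notes, paste(
      "bacteria-only graph is disconnected;",
      "APL values average over reachable bacteria pairs only"
    ))
  }
  if (length(viruses) == 0L) {
    return(new("KeyVirusReport",
      additions = data.frame(
        rank = integer(), node = character(), betweenness = numeric(),
        aplAfter = numeric(), stringsAsFactors = FALSE
      ),
      selected = character(), baselineApl = baseline, notes = notes
    ))
  }
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE,
    weights = NA)
  vb <- btw[match(viruses, igraph::V(graph)$name)]
  ord <- order(-vb, viruses)
  viruses <- viruses[ord]
  vb <- vb[ord]
  apl_after <- numeric(length(viruses))
  current <- bacteria
  for (k in seq_along(viruses)) {
    current <- c(current, viruses[k])
    sub <- igraph::induced_subgraph(graph,
      match(current, igraph::V(graph)$name))
    apl_after[k] <- bacterialApl(sub, bacteria)
  }
  trajectory <- c(baseline, apl_after)
  best <- which.min(trajectory) # first index attaining the minimum
  selected <- if (best == 1L) character() else viruses[seq_len(best - 1L)]
  new("KeyVirusReport",
    additions = data.frame(
      rank = seq_along(viruses), node = viruses, betweenness = vb,
      aplAfter = apl_after, stringsAsFactors = FALSE
    ),
    selected = selected, baselineApl = baseline, notes = notes
  )
}
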