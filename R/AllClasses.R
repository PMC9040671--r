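#' @import methods
#' @importFrom stats var cov quantile sd p.adjust wilcox.test t.test ks.test
#'   fisher.test prop.test cor cor.test rmultinom runif lm coef phyper
#' @importFrom utils read.delim write.table head combn
NULL

setOldClass("igraph")

## ---------------------------------------------------------------------------
## Abundance container
## ---------------------------------------------------------------------------

#' AbundanceMatrix: feature-by-sample abundance values with annotations
#'
#' The central abundance container: a numeric feature x sample matrix tagged
#' with the scale of its values (`count`, `rpk`, or `relative`) and a
#' feature annotation table (name, class, genus, family, phylum).
#'
#' @slot values numeric matrix, features as rows, samples as columns.
#' @slot kind one of `"count"`, `"rpk"`, `"relative"`. `relative` matrices
#'   close to 1 per sample.
#' @slot annotations data.frame with one row per feature; must contain a
#'   `name` column aligned with `rownames(values)`.
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix",
  slots = c(values = "matrix", kind = "character", annotations = "data.frame")
)

setValidity("AbundanceMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "'values' must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v))) {
    msgs <- c(msgs, "'values' must have unique rownames (feature ids)")
  }
  if (is.null(colnames(v)) || anyDuplicated(colnames(v))) {
    msgs <- c(msgs, "'values' must have unique colnames (sample ids)")
  }
  if (length(object@kind) != 1L ||
    !object@kind %in% c("count", "rpk", "relative")) {
    msgs <- c(msgs, "'kind' must be one of count, rpk, relative")
  }
  if (any(v < 0, na.rm = TRUE)) msgs <- c(msgs, "negative abundance values")
  if (identical(object@kind, "relative") && ncol(v) > 0L) {
    cs <- colSums(v)
    if (any(abs(cs - 1) > 1e-9)) {
      msgs <- c(msgs, "relative matrix columns must sum to 1 (+- 1e-9)")
    }
  }
  ann <- object@annotations
  if (nrow(ann) > 0L) {
    if (!"name" %in% names(ann)) {
      msgs <- c(msgs, "annotations must have a 'name' column")
    } else if (!identical(as.character(ann$name), rownames(v))) {
      msgs <- c(msgs, "annotation rows must align with feature rownames")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param kind `"count"`, `"rpk"`, or `"relative"`.
#' @param annotations optional feature annotation data.frame with a `name`
#'   column matching `rownames(values)`; a minimal one is built if omitted.
#' @return An [AbundanceMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' AbundanceMatrix(m, "count")
AbundanceMatrix <- function(values, kind = c("count", "rpk", "relative"),
                            annotations = NULL) {
  kind <- match.arg(kind)
  storage.mode(values) <- "double"
  if (is.null(annotations)) {
    annotations <- data.frame(
      name = rownames(values),
      class = "unclassified",
      genus = rownames(values),
      family = rownames(values),
      phylum = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    annotations <- annotations[match(rownames(values), annotations$name), ,
      drop = FALSE
    ]
    if (anyNA(annotations$name)) {
      stop("annotations missing for features: ",
        paste(setdiff(rownames(values), annotations$name), collapse = ", "),
        call. = FALSE
      )
    }
    rownames(annotations) <- NULL
  }
  new("AbundanceMatrix", values = values, kind = kind,
    annotations = annotations)
}

## ---------------------------------------------------------------------------
## Synthetic-cohort specification objects
## ---------------------------------------------------------------------------

#' TaxaSpec: labelled taxa with log-normal basis parameters
#'
#' Declares the taxa of a synthetic community: their class
#' (bacteria / phage / eukaryotic_virus), genus/family/phylum labels and the
#' per-taxon log-mean and log-sd of the latent (basis) absolute abundance.
#'
#' @slot taxa data.frame with columns name, class, genus, family, phylum.
#' @slot logMean numeric, per-taxon mean of log basis abundance.
#' @slot logSd numeric, per-taxon positive sd of log basis abundance.
#' @exportClass TaxaSpec
setClass("TaxaSpec",
  slots = c(taxa = "data.frame", logMean = "numeric", logSd = "numeric")
)

setValidity("TaxaSpec", function(object) {
  msgs <- character()
  need <- c("name", "class", "genus", "family", "phylum")
  if (!all(need %in% names(object@taxa))) {
    msgs <- c(msgs, paste(
      "taxa table needs columns:", paste(need, collapse = ", ")
    ))
  } else {
    if (anyDuplicated(object@taxa$name)) {
      msgs <- c(msgs, "taxon names must be unique")
    }
    bad <- setdiff(unique(object@taxa$class), .CLASS_LEVELS)
    if (length(bad)) {
      msgs <- c(msgs, paste("unknown class labels:", paste(bad, collapse = ", ")))
    }
  }
  n <- nrow(object@taxa)
  if (length(object@logMean) != n || length(object@logSd) != n) {
    msgs <- c(msgs, "logMean/logSd must have one entry per taxon")
  }
  if (any(object@logSd <= 0)) msgs <- c(msgs, "logSd must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TaxaSpec
#'
#' @param taxa data.frame with columns name, class, genus, family, phylum.
#' @param logMean,logSd per-taxon log-normal basis parameters (recycled if
#'   scalar).
#' @return A [TaxaSpec-class] object.
#' @export
TaxaSpec <- function(taxa, logMean = 0, logSd = 1) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  n <- nrow(taxa)
  new("TaxaSpec",
    taxa = taxa,
    logMean = rep_len(as.numeric(logMean), n),
    logSd = rep_len(as.numeric(logSd), n)
  )
}

#' CorrelationStructure: planted basis correlations between named taxa
#'
#' Declares target basis correlations for selected taxon pairs (background 0).
#' The implied correlation matrix must be positive semi-definite; invalid
#' structures are rejected at construction, naming the first offending leading
#' principal minor, so no cohort is ever generated from an unintended
#' covariance.
#'
#' @slot taxa character vector of taxon names (fixes matrix order).
#' @slot pairs data.frame with columns taxon_i, taxon_j, r.
#' @exportClass CorrelationStructure
setClass("CorrelationStructure",
  slots = c(taxa = "character", pairs = "data.frame")
)

# Build the full correlation matrix a structure implies.
corStructureMatrix <- function(taxa, pairs) {
  D <- length(taxa)
  R <- diag(1, D)
  dimnames(R) <- list(taxa, taxa)
  if (nrow(pairs)) {
    i <- match(pairs$taxon_i, taxa)
    j <- match(pairs$taxon_j, taxa)
    for (k in seq_along(i)) {
      R[i[k], j[k]] <- R[j[k], i[k]] <- pairs$r[k]
    }
  }
  R
}

setValidity("CorrelationStructure", function(object) {
  msgs <- character()
  if (anyDuplicated(object@taxa)) msgs <- c(msgs, "taxa must be unique")
  p <- object@pairs
  need <- c("taxon_i", "taxon_j", "r")
  if (!all(need %in% names(p))) {
    return(paste("pairs needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(p)) {
    unknown <- setdiff(c(p$taxon_i, p$taxon_j), object@taxa)
    if (length(unknown)) {
      msgs <- c(msgs, paste("pairs reference unknown taxa:",
        paste(unique(unknown), collapse = ", ")))
    }
    if (any(p$taxon_i == p$taxon_j)) {
      msgs <- c(msgs, "a pair cannot correlate a taxon with itself")
    }
    if (any(abs(p$r) > 1)) msgs <- c(msgs, "target correlations must be in [-1, 1]")
    if (anyDuplicated(edgeKey(p$taxon_i, p$taxon_j))) {
      msgs <- c(msgs, "duplicate taxon pairs in correlation structure")
    }
  }
  if (!length(msgs)) {
    R <- corStructureMatrix(object@taxa, p)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      # locate the first leading principal minor that fails
      bad <- NA_integer_
      for (k in seq_len(nrow(R))) {
        ek <- eigen(R[seq_len(k), seq_len(k), drop = FALSE],
          symmetric = TRUE, only.values = TRUE
        )$values
        if (min(ek) < -1e-8) {
          bad <- k
          break
        }
      }
      msgs <- c(msgs, sprintf(
        "implied correlation matrix is not positive semi-definite (leading principal minor of order %d fails)",
        bad
      ))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CorrelationStructure
#'
#' @param taxa character vector of taxon names.
#' @param pairs data.frame with columns taxon_i, taxon_j, r (may be empty for
#'   an all-independent structure).
#' @return A [CorrelationStructure-class] object; construction fails if the
#'   implied matrix is not positive semi-definite.
#' @export
CorrelationStructure <- function(taxa, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(
      taxon_i = character(), taxon_j = character(), r = numeric(),
      stringsAsFactors = FALSE
    )
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  new("CorrelationStructure", taxa = as.character(taxa), pairs = pairs)
}

#' CohortSpec: paired case/control synthetic cohort definition
#'
#' Control and case arms share one taxa list; each arm has its own planted
#' correlation structure, sample size and sequencing depth. `differentialPairs`
#' records which planted pairs are meant to differ between arms.
#'
#' @slot taxa a [TaxaSpec-class].
#' @slot controlCor,caseCor [CorrelationStructure-class] over the same taxa.
#' @slot nControl,nCase integer sample counts.
#' @slot depthControl,depthCase per-sample multinomial read depth.
#' @slot differentialPairs data.frame (taxon_i, taxon_j) subset of declared
#'   pairs.
#' @slot seed integer root seed for generation.
#' @exportClass CohortSpec
setClass("CohortSpec",
  slots = c(
    taxa = "TaxaSpec", controlCor = "CorrelationStructure",
    caseCor = "CorrelationStructure", nControl = "integer", nCase = "integer",
    depthControl = "numeric", depthCase = "numeric",
    differentialPairs = "data.frame", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  nm <- object@taxa@taxa$name
  if (!identical(object@controlCor@taxa, nm) ||
    !identical(object@caseCor@taxa, nm)) {
    msgs <- c(msgs, "control and case structures must cover the shared taxa list")
  }
  if (object@nControl < 2L || object@nCase < 2L) {
    msgs <- c(msgs, "each arm needs at least 2 samples")
  }
  if (object@depthControl < 1 || object@depthCase < 1) {
    msgs <- c(msgs, "depth must be >= 1")
  }
  dp <- object@differentialPairs
  if (nrow(dp)) {
    declared <- unique(c(
      edgeKey(object@controlCor@pairs$taxon_i, object@controlCor@pairs$taxon_j),
      edgeKey(object@caseCor@pairs$taxon_i, object@caseCor@pairs$taxon_j)
    ))
    if (!all(edgeKey(dp$taxon_i, dp$taxon_j) %in% declared)) {
      msgs <- c(msgs, "differentialPairs must be a subset of declared pairs")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortSpec
#'
#' @param taxa a [TaxaSpec-class].
#' @param controlCor,caseCor [CorrelationStructure-class] objects over the
#'   same taxa (defaults: all-independent).
#' @param nControl,nCase samples per arm.
#' @param depth per-sample read depth, recycled to both arms if scalar.
#' @param differentialPairs data.frame (taxon_i, taxon_j) of pairs planted to
#'   differ between the arms.
#' @param seed integer root seed.
#' @return A [CohortSpec-class] object.
#' @export
CohortSpec <- function(taxa, controlCor = NULL, caseCor = NULL,
                       nControl = 20L, nCase = 20L, depth = 1e5,
                       differentialPairs = NULL, seed = 1L) {
  nm <- taxa@taxa$name
  controlCor <- controlCor %||% CorrelationStructure(nm)
  caseCor <- caseCor %||% CorrelationStructure(nm)
  depth <- rep_len(depth, 2L)
  if (is.null(differentialPairs)) {
    differentialPairs <- data.frame(
      taxon_i = character(), taxon_j = character(), stringsAsFactors = FALSE
    )
  }
  new("CohortSpec",
    taxa = taxa, controlCor = controlCor, caseCor = caseCor,
    nControl = as.integer(nControl), nCase = as.integer(nCase),
    depthControl = depth[1L], depthCase = depth[2L],
    differentialPairs = as.data.frame(differentialPairs,
      stringsAsFactors = FALSE),
    seed = as.integer(seed)
  )
}

## ---------------------------------------------------------------------------
## Correlation result and network containers
## ---------------------------------------------------------------------------

#' CorrelationResult: basis correlations with shuffled-matrix pseudo p-values
#'
#' @slot r symmetric correlation matrix (unit diagonal, clamped to \[-1, 1\];
#'   NA marks features whose basis variance could not be estimated).
#' @slot p symmetric two-sided pseudo p-value matrix from shuffled data.
#' @slot q Benjamini-Hochberg adjusted p over the upper triangle.
#' @slot shuffled list of correlation matrices, one per shuffle.
#' @slot params list: pseudocount, exclusionThreshold, maxExclusionIters,
#'   nShuffles, seed.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(
    r = "matrix", p = "matrix", q = "matrix", shuffled = "list",
    params = "list"
  )
)

setValidity("CorrelationResult", function(object) {
  msgs <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msgs <- c(msgs, "r must be square")
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-12) {
    msgs <- c(msgs, "r must be symmetric")
  }
  if (any(abs(diag(r)) != 1, na.rm = TRUE)) {
    msgs <- c(msgs, "diag(r) must be 1")
  }
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) msgs <- c(msgs, "|r| must be <= 1")
  ns <- object@params$nShuffles %||% length(object@shuffled)
  if (length(object@shuffled) != ns) {
    msgs <- c(msgs, "shuffled archive length must equal nShuffles")
  }
  if (length(msgs)) msgs else TRUE
})

#' MicrobialNetwork: annotated undirected co-occurrence graph
#'
#' Wraps a simple undirected igraph whose vertices carry taxon annotations
#' (class, genus, family, phylum) and whose edges carry the correlation `r`,
#' pseudo p-value `p`, FDR `q` and `sign` (positive/negative).
#'
#' @slot graph an igraph object.
#' @slot group provenance tag (e.g. "IBS_case").
#' @exportClass MicrobialNetwork
setClass("MicrobialNetwork", slots = c(graph = "igraph", group = "character"))

setValidity("MicrobialNetwork", function(object) {
  g <- object@graph
  msgs <- character()
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (!igraph::is_simple(g)) {
    msgs <- c(msgs, "graph must be simple (no loops or multi-edges)")
  }
  if (!"name" %in% igraph::vertex_attr_names(g)) {
    msgs <- c(msgs, "vertices must be named")
  }
  if (!"class" %in% igraph::vertex_attr_names(g)) {
    msgs <- c(msgs, "vertices must carry a 'class' attribute")
  } else {
    bad <- setdiff(unique(igraph::V(g)$class), .CLASS_LEVELS)
    if (length(bad)) {
      msgs <- c(msgs, paste("unknown node classes:", paste(bad, collapse = ", ")))
    }
  }
  if (igraph::ecount(g) > 0L) {
    ea <- igraph::edge_attr_names(g)
    if (!"sign" %in% ea) {
      msgs <- c(msgs, "edges must carry a 'sign' attribute")
    } else {
      sgn <- igraph::E(g)$sign
      if (!all(sgn %in% c("positive", "negative"))) {
        msgs <- c(msgs, "edge sign must be positive/negative")
      }
      if ("r" %in% ea) {
        r <- igraph::E(g)$r
        ok <- is.na(r) | (r > 0 & sgn == "positive") | (r < 0 & sgn == "negative")
        if (!all(ok)) msgs <- c(msgs, "edge sign must match sign(r)")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MicrobialNetwork from an igraph
#'
#' Missing vertex annotations are filled with defaults (class
#' `"bacteria"`, genus/family equal to the node name); missing edge signs
#' default to `"positive"`.
#'
#' @param graph a simple undirected igraph with named vertices.
#' @param group provenance tag.
#' @return A [MicrobialNetwork-class].
#' @export
MicrobialNetwork <- function(graph, group = "network") {
  if (!"name" %in% igraph::vertex_attr_names(graph)) {
    igraph::V(graph)$name <- paste0("n", seq_len(igraph::vcount(graph)))
  }
  va <- igraph::vertex_attr_names(graph)
  if (!"class" %in% va) igraph::V(graph)$class <- "bacteria"
  if (!"genus" %in% va) igraph::V(graph)$genus <- igraph::V(graph)$name
  if (!"family" %in% va) igraph::V(graph)$family <- igraph::V(graph)$name
  if (!"phylum" %in% va) igraph::V(graph)$phylum <- NA_character_
  if (igraph::ecount(graph) > 0L &&
    !"sign" %in% igraph::edge_attr_names(graph)) {
    if ("r" %in% igraph::edge_attr_names(graph)) {
      igraph::E(graph)$sign <- ifelse(igraph::E(graph)$r < 0,
        "negative", "positive")
    } else {
      igraph::E(graph)$sign <- "positive"
    }
  }
  new("MicrobialNetwork", graph = graph, group = group)
}

## ---------------------------------------------------------------------------
## Differential links and key-virus report
## ---------------------------------------------------------------------------

#' DifferentialLinkSet: case-only and significantly shifted shared links
#'
#' @slot caseOnly data.frame of links present only in the case network.
#' @slot sharedSignificant data.frame of links present in both networks whose
#'   correlation difference D exceeds its per-edge bootstrap null quantile.
#' @slot quantileLevel the null quantile level used (default 0.95).
#' @exportClass DifferentialLinkSet
setClass("DifferentialLinkSet",
  slots = c(
    caseOnly = "data.frame", sharedSignificant = "data.frame",
    quantileLevel = "numeric"
  )
)

setValidity("DifferentialLinkSet", function(object) {
  msgs <- character()
  a <- object@caseOnly
  b <- object@sharedSignificant
  if (nrow(a) && nrow(b)) {
    ka <- edgeKey(a$source, a$target)
    kb <- edgeKey(b$source, b$target)
    if (length(intersect(ka, kb))) {
      msgs <- c(msgs, "case-only and shared-significant sets must be disjoint")
    }
  }
  if (nrow(b) && !all(b$D > b$null_quantile)) {
    msgs <- c(msgs, "every shared-significant edge must have D > its null quantile")
  }
  if (length(msgs)) msgs else TRUE
})

#' KeyVirusReport: betweenness-ordered virus addition trajectory
#'
#' @slot additions data.frame (rank, node, betweenness, aplAfter) sorted by
#'   non-increasing full-graph betweenness.
#' @slot selected character vector: the shortest prefix of the addition order
#'   attaining the minimum bacterial average path length.
#' @slot baselineApl average path length of the bacteria-only graph.
#' @slot notes character notes (e.g. disconnected-baseline convention flag).
#' @exportClass KeyVirusReport
setClass("KeyVirusReport",
  slots = c(
    additions = "data.frame", selected = "character",
    baselineApl = "numeric", notes = "character"
  )
)
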