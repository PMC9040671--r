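## Generics, accessors and show methods.

#' Extract the abundance value matrix
#' @param x an [AbundanceMatrix-class].
#' @return numeric matrix, features x samples.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname abundances
#' @export
setMethod("abundances", "AbundanceMatrix", function(x) x@values)

#' Kind of an abundance matrix ("count", "rpk" or "relative")
#' @param x an [AbundanceMatrix-class].
#' @return character scalar.
#' @export
setGeneric("abundanceKind", function(x) standardGeneric("abundanceKind"))

#' @rdname abundanceKind
#' @export
setMethod("abundanceKind", "AbundanceMatrix", function(x) x@kind)

#' Feature annotation table
#' @param x an [AbundanceMatrix-class].
#' @return data.frame with one row per feature.
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname featureData
#' @export
setMethod("featureData", "AbundanceMatrix", function(x) x@annotations)

#' Correlation matrix of a CorrelationResult
#' @param x a [CorrelationResult-class].
#' @return symmetric numeric matrix.
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' @rdname correlations
#' @export
setMethod("correlations", "CorrelationResult", function(x) x@r)

#' Pseudo p-value matrix of a CorrelationResult
#' @param x a [CorrelationResult-class].
#' @return symmetric numeric matrix of two-sided shuffled pseudo p-values.
#' @export
setGeneric("pseudoPValues", function(x) standardGeneric("pseudoPValues"))

#' @rdname pseudoPValues
#' @export
setMethod("pseudoPValues", "CorrelationResult", function(x) x@p)

#' FDR-adjusted p-value matrix of a CorrelationResult
#' @param x a [CorrelationResult-class].
#' @return symmetric numeric matrix of Benjamini-Hochberg q-values.
#' @export
setGeneric("adjustedPValues", function(x) standardGeneric("adjustedPValues"))

#' @rdname adjustedPValues
#' @export
setMethod("adjustedPValues", "CorrelationResult", function(x) x@q)

#' Archive of shuffled-data correlation matrices
#' @param x a [CorrelationResult-class].
#' @return list of matrices, one per shuffle.
#' @export
setGeneric("shuffledArchive", function(x) standardGeneric("shuffledArchive"))

#' @rdname shuffledArchive
#' @export
setMethod("shuffledArchive", "CorrelationResult", function(x) x@shuffled)

#' Underlying igraph of a MicrobialNetwork
#' @param x a [MicrobialNetwork-class].
#' @return an igraph object.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "MicrobialNetwork", function(x) x@graph)

#' Provenance tag of a MicrobialNetwork
#' @param x a [MicrobialNetwork-class].
#' @return character scalar group id.
#' @export
setGeneric("networkGroup", function(x) standardGeneric("networkGroup"))

#' @rdname networkGroup
#' @export
setMethod("networkGroup", "MicrobialNetwork", function(x) x@group)

#' Edge table of a MicrobialNetwork
#' @param x a [MicrobialNetwork-class].
#' @return data.frame with source, target and edge attributes.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "MicrobialNetwork", function(x) edgeTable(x@graph))

#' Node table of a MicrobialNetwork
#' @param x a [MicrobialNetwork-class].
#' @return data.frame with name and vertex attributes.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "MicrobialNetwork", function(x) nodeTable(x@graph))

#' Case-only links of a DifferentialLinkSet
#' @param x a [DifferentialLinkSet-class].
#' @return data.frame of links present only in the case network.
#' @export
setGeneric("caseOnlyLinks", function(x) standardGeneric("caseOnlyLinks"))

#' @rdname caseOnlyLinks
#' @export
setMethod("caseOnlyLinks", "DifferentialLinkSet", function(x) x@caseOnly)

#' Shared links with significantly different correlation
#' @param x a [DifferentialLinkSet-class].
#' @return data.frame of shared links whose difference D exceeds the null
#'   quantile.
#' @export
setGeneric("sharedSignificantLinks",
  function(x) standardGeneric("sharedSignificantLinks"))

#' @rdname sharedSignificantLinks
#' @export
setMethod("sharedSignificantLinks", "DifferentialLinkSet",
  function(x) x@sharedSignificant)

#' Addition trajectory of a KeyVirusReport
#' @param x a [KeyVirusReport-class].
#' @return data.frame (rank, node, betweenness, aplAfter).
#' @export
setGeneric("virusAdditions", function(x) standardGeneric("virusAdditions"))

#' @rdname virusAdditions
#' @export
setMethod("virusAdditions", "KeyVirusReport", function(x) x@additions)

#' Selected key viruses of a KeyVirusReport
#' @param x a [KeyVirusReport-class].
#' @return character vector (shortest APL-minimising prefix).
#' @export
setGeneric("selectedViruses", function(x) standardGeneric("selectedViruses"))

#' @rdname selectedViruses
#' @export
setMethod("selectedViruses", "KeyVirusReport", function(x) x@selected)

#' Baseline bacteria-only average path length
#' @param x a [KeyVirusReport-class].
#' @return numeric scalar.
#' @export
setGeneric("baselineApl", function(x) standardGeneric("baselineApl"))

#' @rdname baselineApl
#' @export
setMethod("baselineApl", "KeyVirusReport", function(x) x@baselineApl)

## -- show methods -----------------------------------------------------------

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf(
    "AbundanceMatrix: %d features x %d samples (kind = %s)\n",
    nrow(object@values), ncol(object@values), object@kind
  ))
  cls <- table(object@annotations$class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TaxaSpec", function(object) {
  cls <- table(object@taxa$class)
  cat(sprintf("TaxaSpec: %d taxa (%s)\n", nrow(object@taxa),
    paste(names(cls), cls, sep = "=", collapse = ", ")))
})

setMethod("show", "CorrelationStructure", function(object) {
  cat(sprintf(
    "CorrelationStructure: %d taxa, %d planted pair(s)\n",
    length(object@taxa), nrow(object@pairs)
  ))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d taxa; control n=%d depth=%g; case n=%d depth=%g; %d differential pair(s); seed=%d\n",
    nrow(object@taxa@taxa), object@nControl, object@depthControl,
    object@nCase, object@depthCase, nrow(object@differentialPairs),
    object@seed
  ))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf(
    "CorrelationResult: %d features, %d shuffles; |r| range %.3f-%.3f (off-diagonal)\n",
    nrow(object@r), length(object@shuffled),
    min(abs(object@r[upper.tri(object@r)]), na.rm = TRUE),
    max(abs(object@r[upper.tri(object@r)]), na.rm = TRUE)
  ))
})

setMethod("show", "MicrobialNetwork", function(object) {
  g <- object@graph
  neg <- if (igraph::ecount(g)) sum(igraph::E(g)$sign == "negative") else 0L
  cat(sprintf(
    "MicrobialNetwork '%s': %d nodes, %d edges (%d negative)\n",
    object@group, igraph::vcount(g), igraph::ecount(g), neg
  ))
})

setMethod("show", "DifferentialLinkSet", function(object) {
  cat(sprintf(
    "DifferentialLinkSet: %d case-only link(s), %d shared link(s) beyond the %.0f%% null quantile\n",
    nrow(object@caseOnly), nrow(object@sharedSignificant),
    100 * object@quantileLevel
  ))
})

setMethod("show", "KeyVirusReport", function(object) {
  cat(sprintf(
    "KeyVirusReport: baseline bacterial APL %.4f; %d virus(es) ranked; %d selected\n",
    object@baselineApl, nrow(object@additions), length(object@selected)
  ))
  if (length(object@notes)) cat("  note:", object@notes, "\n")
})
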