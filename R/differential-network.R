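## Disease-specific differential networks.
##
## Two categories make up a disease-specific network: (A) links present only
## in the case group's network, and (B) links present in both networks whose
## correlation difference D = |r_case - r_control| exceeds the 95% quantile
## of a per-edge bootstrap null built from the shuffled correlation archive.

#' Build a disease-specific (or healthy-specific) network
#'
#' Category A collects edges of the case network absent from the control
#' network (existence meaning survival of that network's r/q thresholds).
#' Category B collects shared edges whose observed difference
#' `D = |r_case - r_control|` exceeds the empirical `quantile` of the null
#' differences `|r_case - r_shuffled_k|`, computed per edge from the shuffled
#' archive of the comparison arm (`nullSource = "control"`, the default) or
#' from both arms' archives pooled (`nullSource = "pooled"`). Swapping the
#' case and control arguments yields the healthy-specific network.
#'
#' @param caseNetwork,controlNetwork [MicrobialNetwork-class] objects built
#'   over a shared feature vocabulary.
#' @param caseResult,controlResult the matching [CorrelationResult-class]
#'   objects; the null-source result must carry a shuffled archive.
#' @param quantile null quantile level (default 0.95).
#' @param nullSource `"control"` or `"pooled"`.
#' @return list with `links` (a [DifferentialLinkSet-class]) and `network`
#'   (a [MicrobialNetwork-class] of the A-union-B edges, edge attribute
#'   `category` in `{case_only, shared_diff}`).
#' @export
buildDiseaseSpecificNetwork <- function(caseNetwork, caseResult,
                                        controlNetwork, controlResult,
                                        quantile = 0.95,
                                        nullSource = c("control", "pooled")) {
  nullSource <- match.arg(nullSource)
  stopifnot(
    is(caseNetwork, "MicrobialNetwork"), is(controlNetwork, "MicrobialNetwork"),
    is(caseResult, "CorrelationResult"), is(controlResult, "CorrelationResult")
  )
  checkRange(quantile, "quantile", 0, 1, lo_open = TRUE, hi_open = TRUE)
  archive <- switch(nullSource,
    control = controlResult@shuffled,
    pooled = c(controlResult@shuffled, caseResult@shuffled)
  )
  if (length(archive) == 0L) {
    stop("the null-source correlation result carries no shuffled archive",
      call. = FALSE
    )
  }
  ce <- edgeTable(caseNetwork@graph)
  oe <- edgeTable(controlNetwork@graph)
  if (!"r" %in% names(ce)) ce$r <- rep(NA_real_, nrow(ce))
  if (!"r" %in% names(oe)) oe$r <- rep(NA_real_, nrow(oe))
  ckey <- edgeKey(ce$source, ce$target)
  okey <- edgeKey(oe$source, oe$target)
  vocab <- rownames(controlResult@r)
  missing_endpoint <- !(ce$source %in% vocab & ce$target %in% vocab)
  if (any(missing_endpoint)) {
    warning(sum(missing_endpoint),
      " case edge(s) have endpoints absent from the control vocabulary;",
      " treated as case-only",
      call. = FALSE
    )
  }
  shared <- ckey %in% okey & !missing_endpoint
  case_only <- ce[!shared, c("source", "target", "r"), drop = FALSE]
  names(case_only)[3L] <- "r_case"
  rownames(case_only) <- NULL

  sh <- ce[shared, , drop = FALSE]
  if (nrow(sh)) {
    m <- match(edgeKey(sh$source, sh$target), okey)
    r_ctrl <- oe$r[m]
    null_q <- numeric(nrow(sh))
    for (k in seq_len(nrow(sh))) {
      i <- match(sh$source[k], vocab)
      j <- match(sh$target[k], vocab)
      nulls <- vapply(archive, function(rm) rm[i, j], numeric(1))
      diffs <- abs(sh$r[k] - nulls)
      null_q[k] <- stats::quantile(diffs, quantile, na.rm = TRUE,
        names = FALSE)
    }
    D <- abs(sh$r - r_ctrl)
    shared_df <- data.frame(
      source = sh$source, target = sh$target,
      r_case = sh$r, r_control = r_ctrl, D = D, null_quantile = null_q,
      stringsAsFactors = FALSE
    )
    shared_sig <- shared_df[shared_df$D > shared_df$null_quantile, ,
      drop = FALSE
    ]
    rownames(shared_sig) <- NULL
  } else {
    shared_sig <- data.frame(
      source = character(), target = character(), r_case = numeric(),
      r_control = numeric(), D = numeric(), null_quantile = numeric(),
      stringsAsFactors = FALSE
    )
  }
  links <- new("DifferentialLinkSet",
    caseOnly = case_only, sharedSignificant = shared_sig,
    quantileLevel = quantile
  )
  keep_keys <- c(
    edgeKey(case_only$source, case_only$target),
    edgeKey(shared_sig$source, shared_sig$target)
  )
  g <- caseNetwork@graph
  if (igraph::ecount(g)) {
    all_keys <- edgeKey(ce$source, ce$target)
    g <- igraph::subgraph_from_edges(g,
      igraph::E(g)[all_keys %in% keep_keys],
      delete.vertices = TRUE
    )
    if (igraph::ecount(g)) {
      gk <- edgeKey(
        igraph::as_edgelist(g)[, 1L],
        igraph::as_edgelist(g)[, 2L]
      )
      igraph::E(g)$category <- ifelse(
        gk %in% edgeKey(case_only$source, case_only$target),
        "case_only", "shared_diff"
      )
    }
  }
  network <- MicrobialNetwork(g,
    group = paste0(caseNetwork@group, "_specific"))
  list(links = links, network = network)
}
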