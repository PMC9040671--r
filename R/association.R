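## Differential features, cross-feature correlations, link-sign permutation
## enrichment and Fisher functional enrichment.

#' Per-feature differential abundance tests between two arms
#'
#' Runs a two-sided Mann-Whitney U (Wilcoxon rank-sum) or Welch t-test for
#' every shared feature. Features constant in both arms get p = 1 with a
#' degeneracy flag. For the t-test a Kolmogorov-Smirnov normality check of
#' the standardized values is attached per arm.
#'
#' @param case,control [AbundanceMatrix-class] objects (or matrices) over a
#'   shared feature vocabulary, >= 3 samples per arm.
#' @param test `"mann_whitney"` (default) or `"welch_t"`.
#' @param alpha significance level used to call the direction (default
#'   0.05).
#' @return data.frame with feature, test, statistic, p, direction
#'   (`enriched` = higher in case, `depleted`; NA when p > alpha),
#'   degenerate flag and (for the t-test) KS normality p-values.
#' @export
differentialFeatures <- function(case, control,
                                 test = c("mann_whitney", "welch_t"),
                                 alpha = 0.05) {
  test <- match.arg(test)
  a <- if (is(case, "AbundanceMatrix")) case@values else as.matrix(case)
  b <- if (is(control, "AbundanceMatrix")) control@values else as.matrix(control)
  shared <- intersect(rownames(a), rownames(b))
  if (!length(shared)) stop("no shared features", call. = FALSE)
  if (ncol(a) < 3L || ncol(b) < 3L) {
    stop("need at least 3 samples per arm", call. = FALSE)
  }
  ks_norm <- function(x) {
    if (stats::sd(x) == 0) {
      return(NA_real_)
    }
    suppressWarnings(stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value)
  }
  rows <- lapply(shared, function(f) {
    x <- a[f, ]
    y <- b[f, ]
    degenerate <- stats::sd(c(x, y)) == 0
    if (degenerate) {
      stat <- NA_real_
      p <- 1
    } else if (test == "mann_whitney") {
      ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
      stat <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    centre_diff <- if (test == "mann_whitney") {
      stats::median(x) - stats::median(y)
    } else {
      mean(x) - mean(y)
    }
    direction <- if (!degenerate && p <= alpha) {
      if (centre_diff > 0) "enriched" else "depleted"
    } else {
      NA_character_
    }
    out <- data.frame(
      feature = f, test = test, statistic = stat, p = p,
      direction = direction, degenerate = degenerate,
      stringsAsFactors = FALSE
    )
    if (test == "welch_t") {
      out$ks_normality_p_case <- ks_norm(x)
      out$ks_normality_p_control <- ks_norm(y)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix between two feature sets
#'
#' Pairwise tie-corrected Spearman correlations between the features of `a`
#' (rows of the result) and `b` (columns), over their shared samples, with
#' Benjamini-Hochberg adjustment over the full matrix. Constant features
#' give NA entries.
#'
#' @param a,b [AbundanceMatrix-class] objects or feature x sample matrices
#'   with >= 4 shared samples.
#' @return list of matrices `r`, `p`, `q` (features of `a` x features of
#'   `b`).
#' @export
correlationHeatmapTable <- function(a, b) {
  ma <- if (is(a, "AbundanceMatrix")) a@values else as.matrix(a)
  mb <- if (is(b, "AbundanceMatrix")) b@values else as.matrix(b)
  samples <- intersect(colnames(ma), colnames(mb))
  if (length(samples) < 4L) {
    stop("need at least 4 shared samples", call. = FALSE)
  }
  ma <- ma[, samples, drop = FALSE]
  mb <- mb[, samples, drop = FALSE]
  nr <- nrow(ma)
  nc <- nrow(mb)
  r <- matrix(NA_real_, nr, nc, dimnames = list(rownames(ma), rownames(mb)))
  p <- r
  for (i in seq_len(nr)) {
    if (stats::sd(ma[i, ]) == 0) next
    for (j in seq_len(nc)) {
      if (stats::sd(mb[j, ]) == 0) next
      ht <- suppressWarnings(
        stats::cor.test(ma[i, ], mb[j, ], method = "spearman")
      )
      r[i, j] <- unname(ht$estimate)
      p[i, j] <- ht$p.value
    }
  }
  q <- p
  q[] <- stats::p.adjust(p, method = "BH")
  list(r = r, p = p, q = q)
}

#' Link-sign permutation enrichment per bacterial phylum
#'
#' For a network, counts all bacteria-virus links (n1) and the negative ones
#' (n2); per bacterial phylum, the observed negative phylum-virus links (n3)
#' are compared with the null obtained by drawing n2 links without
#' replacement from the n1 bacteria-virus links `nPerm` times and counting
#' phylum links among the draw. Two-sided p doubles the smaller tail
#' (add-one estimator, capped at 1), with Benjamini-Hochberg adjustment
#' across phyla. Also reports the negative-link ratio within and between
#' the three node classes with pairwise two-proportion chi-square
#' comparisons (continuity-corrected, BH-adjusted).
#'
#' @param g a [MicrobialNetwork-class] with >= 1 bacteria-virus link and
#'   phylum labels on bacteria nodes.
#' @param nPerm number of permutation draws (default 100000).
#' @param seed integer seed.
#' @return list with `phylumTable` (phylum, n1, n2, n3, p, q),
#'   `ratioTable` (class-pair edge counts, negative counts and ratios) and
#'   `ratioComparisons` (pairwise proportion-test p/q).
#' @export
linkSignEnrichment <- function(g, nPerm = 100000L, seed = 1L) {
  stopifnot(is(g, "MicrobialNetwork"), nPerm >= 1L)
  graph <- g@graph
  et <- edgeTable(graph)
  if (nrow(et) == 0L) stop("network has no edges", call. = FALSE)
  cls <- igraph::V(graph)$class
  phy <- igraph::V(graph)$phylum
  nm <- igraph::V(graph)$name
  cs <- cls[match(et$source, nm)]
  ct <- cls[match(et$target, nm)]

  ## class-pair negative-ratio table over ALL edges
  pair_lab <- paste(pmin(cs, ct), pmax(cs, ct), sep = "--")
  ratioTable <- do.call(rbind, lapply(split(et$sign, pair_lab), function(s) {
    data.frame(
      edges = length(s), negative = sum(s == "negative"),
      negative_ratio = mean(s == "negative"), stringsAsFactors = FALSE
    )
  }))
  ratioTable <- data.frame(
    class_pair = rownames(ratioTable), ratioTable,
    row.names = NULL, stringsAsFactors = FALSE
  )
  comp <- NULL
  if (nrow(ratioTable) >= 2L) {
    idx <- utils::combn(nrow(ratioTable), 2L)
    comp <- data.frame(
      pair_a = ratioTable$class_pair[idx[1L, ]],
      pair_b = ratioTable$class_pair[idx[2L, ]],
      p = vapply(seq_len(ncol(idx)), function(k) {
        i <- idx[1L, k]
        j <- idx[2L, k]
        suppressWarnings(stats::prop.test(
          c(ratioTable$negative[i], ratioTable$negative[j]),
          c(ratioTable$edges[i], ratioTable$edges[j]),
          correct = TRUE
        )$p.value)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    comp$q <- stats::p.adjust(comp$p, method = "BH")
  }

  ## phylum permutation test over bacteria-virus links
  bv <- (cs == "bacteria" & ct %in% .VIRUS_CLASSES) |
    (ct == "bacteria" & cs %in% .VIRUS_CLASSES)
  if (!any(bv)) stop("network has no bacteria-virus link", call. = FALSE)
  bve <- et[bv, , drop = FALSE]
  bact_end <- ifelse(cs[bv] == "bacteria", bve$source, bve$target)
  bact_phy <- phy[match(bact_end, nm)]
  n1 <- nrow(bve)
  neg <- bve$sign == "negative"
  n2 <- sum(neg)
  phyla <- sort(unique(bact_phy[!is.na(bact_phy)]))
  excluded <- character()
  if (anyNA(bact_phy)) {
    excluded <- c(excluded, "links from bacteria without phylum annotation")
  }
  if (!length(phyla)) {
    stop("no phylum labels on bacteria endpoints", call. = FALSE)
  }
  ind <- vapply(phyla, function(ph) !is.na(bact_phy) & bact_phy == ph,
    logical(n1))
  ind <- matrix(ind, nrow = n1)
  n3 <- as.integer(colSums(ind & neg))
  ge <- integer(length(phyla)) # draws with n4 >= n3
  le <- integer(length(phyla))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      idx <- sample.int(n1, n2)
      n4 <- colSums(ind[idx, , drop = FALSE])
      ge <- ge + (n4 >= n3)
      le <- le + (n4 <= n3)
    }
  })
  upper <- (1 + ge) / (1 + nPerm)
  lower <- (1 + le) / (1 + nPerm)
  pvals <- pmin(1, 2 * pmin(upper, lower))
  phylumTable <- data.frame(
    phylum = phyla, n1 = n1, n2 = n2, n3 = n3,
    p = pvals, q = stats::p.adjust(pvals, method = "BH"),
    stringsAsFactors = FALSE
  )
  rownames(phylumTable) <- NULL
  list(
    phylumTable = phylumTable, ratioTable = ratioTable,
    ratioComparisons = comp, excluded = excluded,
    params = list(nPerm = as.integer(nPerm), seed = as.integer(seed))
  )
}

#' Fisher's exact enrichment of function categories
#'
#' Per category, a one-sided (greater) Fisher exact test of a 2x2
#' contingency table comparing the category's share of the subset with its
#' share of the background. `mode = "complement"` (default, statistically
#' standard) uses disjoint columns subset vs background-minus-subset;
#' `mode = "as_printed"` uses subset vs the full background. BH adjustment
#' across categories.
#'
#' @param subsetCounts named integer vector: genes per category in the
#'   subset.
#' @param backgroundCounts named integer vector: genes per category in the
#'   background; must cover every subset category.
#' @param mode `"complement"` or `"as_printed"`.
#' @return data.frame (category, subset, background, p, q).
#' @export
fisherCategoryEnrichment <- function(subsetCounts, backgroundCounts,
                                     mode = c("complement", "as_printed")) {
  mode <- match.arg(mode)
  missing_cat <- setdiff(names(subsetCounts), names(backgroundCounts))
  if (length(missing_cat)) {
    stop("categories absent from background: ",
      paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  cats <- names(backgroundCounts)
  sub <- ifelse(cats %in% names(subsetCounts), subsetCounts[cats], 0L)
  sub[is.na(sub)] <- 0L
  bg <- as.integer(backgroundCounts)
  if (mode == "complement" && any(sub > bg)) {
    stop("subset counts exceed background counts in complement mode",
      call. = FALSE)
  }
  other <- if (mode == "complement") bg - sub else bg
  sub_tot <- sum(sub)
  other_tot <- sum(other)
  p <- vapply(seq_along(cats), function(k) {
    tab <- matrix(c(
      sub[k], other[k],
      sub_tot - sub[k], other_tot - other[k]
    ), 2L, 2L, byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  data.frame(
    category = cats, subset = as.integer(sub), background = bg,
    p = p, q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
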