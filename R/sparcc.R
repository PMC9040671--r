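## Basis (SparCC-style) correlation estimation for compositional counts.
##
## Relative abundances sum to 1 per sample, so naive correlations of
## fractions are biased negative. The basis-correlation estimator works on
## log-ratios instead: with t_ij = Var_samples[log(f_i / f_j)] (the variation
## matrix) and basis variances w_i, t_ij = w_i + w_j - 2 r_ij sqrt(w_i w_j).
## Under the sparsity approximation (most true correlations near zero) the
## row sums of t give a linear system for w, and
##   r_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)).
## Strongly correlated pairs violate the approximation, so the estimator
## iteratively excludes the most-correlated pair above a threshold from the
## variance system and re-solves.

# Variation matrix t_ij = var(log f_i - log f_j) over samples, from a
# D x n log-fraction matrix. Computed via the covariance identity.
variationMatrix <- function(logf) {
  C <- stats::cov(t(logf))
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  diag(t_mat) <- 0
  (t_mat + t(t_mat)) / 2
}

# Core single-matrix estimator on a counts matrix (features x samples).
basisCorrelationCore <- function(x, pseudocount, exclusionThreshold,
                                 maxExclusionIters) {
  D <- nrow(x)
  x[x == 0] <- pseudocount
  f <- sweep(x, 2L, colSums(x), "/")
  t_mat <- variationMatrix(log(f))

  # sparse-approximation linear system: M w = rowSums(t)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  T_vec <- rowSums(t_mat)
  Minv <- solve(M)
  w <- drop(Minv %*% T_vec)

  corFromW <- function(w) {
    sw <- sqrt(pmax(w, 0))
    r <- (outer(w, w, "+") - t_mat) / (2 * outer(sw, sw))
    r[!is.finite(r)] <- NA
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  # |r| without clamping, for in-loop max finding only (ordering above the
  # threshold is unaffected by the clamp)
  absR <- function(w) {
    sw <- sqrt(pmax(w, 0))
    a <- abs((outer(w, w, "+") - t_mat) / (2 * outer(sw, sw)))
    a[!is.finite(a)] <- NA
    a
  }

  # masked candidate matrix: NA marks unavailable pairs
  mask <- matrix(FALSE, D, D)
  diag(mask) <- TRUE
  excl_count <- integer(D)
  iter <- 0L
  while (iter < maxExclusionIters) {
    cand <- absR(w)
    cand[mask] <- NA
    mx <- suppressWarnings(max(cand, na.rm = TRUE))
    if (!is.finite(mx) || mx <= exclusionThreshold) break
    ij <- arrayInd(which.max(cand), dim(cand))
    i <- ij[1L]
    j <- ij[2L]
    mask[i, j] <- mask[j, i] <- TRUE
    excl_count[i] <- excl_count[i] + 1L
    excl_count[j] <- excl_count[j] + 1L
    # features excluded from nearly every pair leave the exclusion pool
    exh <- excl_count >= D - 3L
    if (any(exh)) {
      mask[exh, ] <- TRUE
      mask[, exh] <- TRUE
    }
    # the pair exclusion is a symmetric rank-1 downdate M' = M - vv',
    # updated via Sherman-Morrison on the inverse
    v <- Minv[, i] + Minv[, j] # = Minv %*% (e_i + e_j), Minv symmetric
    denom <- 1 - (v[i] + v[j])
    if (abs(denom) < 1e-10) break # downdate would make the system singular
    Minv <- Minv + tcrossprod(v) / denom
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    T_vec[i] <- T_vec[i] - t_mat[i, j]
    T_vec[j] <- T_vec[j] - t_mat[i, j]
    iter <- iter + 1L
    if (iter %% 200L == 0L) Minv <- solve(M) # curb rank-1 update drift
    w <- drop(Minv %*% T_vec)
  }
  r <- corFromW(w)

  bad <- w <= 0
  if (any(bad)) {
    warning(
      "negative basis variance for feature(s) ",
      paste(rownames(x)[bad], collapse = ", "),
      "; their correlations are reported as NA",
      call. = FALSE
    )
    r[bad, ] <- NA
    r[, bad] <- NA
    diag(r) <- 1
  }
  dimnames(r) <- list(rownames(x), rownames(x))
  r
}

#' Estimate basis correlations of compositional count data
#'
#' Implements the log-ratio basis-correlation estimator with iterative
#' strong-pair exclusion. A pseudocount is added to zero cells before closure
#' so log-ratios are defined.
#'
#' @param counts an [AbundanceMatrix-class] of kind `"count"` (or a plain
#'   numeric matrix, features x samples) with at least 4 features and 3
#'   samples.
#' @param pseudocount value added to zero counts (default 1).
#' @param exclusionThreshold correlation magnitude above which the
#'   most-correlated pair is excluded from the basis-variance system and the
#'   system re-solved (default 0.1); set to 1 to disable exclusion.
#' @param maxExclusionIters safety cap on exclusion iterations; default
#'   D(D-1)/2 (one per pair).
#' @return Symmetric correlation matrix in \[-1, 1\] with unit diagonal.
#'   Features whose estimated basis variance is not positive after exclusion
#'   are flagged with a warning and reported as NA.
#' @export
estimateBasisCorrelations <- function(counts, pseudocount = 1,
                                      exclusionThreshold = 0.1,
                                      maxExclusionIters = NULL) {
  x <- if (is(counts, "AbundanceMatrix")) counts@values else as.matrix(counts)
  if (nrow(x) < 4L) {
    stop("need at least 4 features (the basis-variance system is ill-posed below that)",
      call. = FALSE
    )
  }
  if (ncol(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  checkRange(pseudocount, "pseudocount", 0, Inf, lo_open = TRUE)
  checkRange(exclusionThreshold, "exclusionThreshold", 0, 1, lo_open = TRUE)
  D <- nrow(x)
  maxExclusionIters <- maxExclusionIters %||% (D * (D - 1L) %/% 2L)
  basisCorrelationCore(x, pseudocount, exclusionThreshold, maxExclusionIters)
}

#' Basis correlations with shuffled-matrix pseudo p-values
#'
#' Computes the observed basis correlations, then repeats the estimate on
#' shuffled matrices in which every feature's values are independently
#' permuted across samples (destroying correlation, preserving marginals).
#' Two-sided pseudo p-values use the add-one estimator
#' p = (1 + #\{shuffled |r| >= observed |r|\}) / (nShuffles + 1), and
#' Benjamini-Hochberg q-values are computed over the upper triangle.
#'
#' @inheritParams estimateBasisCorrelations
#' @param nShuffles number of shuffled matrices (default 100).
#' @param seed integer seed for the shuffles.
#' @return A [CorrelationResult-class] carrying r, p, q and the shuffled
#'   correlation archive.
#' @export
shuffledPseudoPvalues <- function(counts, nShuffles = 100L, seed = 1L,
                                  pseudocount = 1, exclusionThreshold = 0.1,
                                  maxExclusionIters = NULL) {
  x <- if (is(counts, "AbundanceMatrix")) counts@values else as.matrix(counts)
  stopifnot(nShuffles >= 1L)
  r_obs <- estimateBasisCorrelations(x, pseudocount, exclusionThreshold,
    maxExclusionIters)
  D <- nrow(x)
  maxIters <- maxExclusionIters %||% (D * (D - 1L) %/% 2L)
  shuffled <- withSeed(seed, {
    lapply(seq_len(nShuffles), function(k) {
      xs <- x
      for (i in seq_len(D)) xs[i, ] <- xs[i, sample.int(ncol(xs))]
      suppressWarnings(
        basisCorrelationCore(xs, pseudocount, exclusionThreshold, maxIters)
      )
    })
  })
  exceed <- matrix(0L, D, D)
  valid <- matrix(0L, D, D)
  a_obs <- abs(r_obs)
  for (rs in shuffled) {
    as_ <- abs(rs)
    ok <- !is.na(as_) & !is.na(a_obs)
    exceed <- exceed + ifelse(ok & as_ >= a_obs, 1L, 0L)
    valid <- valid + ifelse(ok, 1L, 0L)
  }
  p <- (1 + exceed) / (1 + valid)
  p[valid == 0 | is.na(a_obs)] <- NA
  diag(p) <- 0
  dimnames(p) <- dimnames(r_obs)
  q <- matrix(NA_real_, D, D, dimnames = dimnames(r_obs))
  ut <- upper.tri(p)
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  new("CorrelationResult",
    r = r_obs, p = p, q = q, shuffled = shuffled,
    params = list(
      pseudocount = pseudocount, exclusionThreshold = exclusionThreshold,
      maxExclusionIters = maxIters, nShuffles = as.integer(nShuffles),
      seed = as.integer(seed)
    )
  )
}

#' Build a co-occurrence network from a correlation result
#'
#' Keeps edges with `|r| >= rMin` and `q <= qMax`; nodes with no surviving
#' edge are dropped. Edge sign records the sign of r. The `"unclassified"`
#' aggregate feature (and any feature of class `"unclassified"` when
#' `excludeUnclassified = TRUE`) is excluded before thresholding.
#'
#' @param result a [CorrelationResult-class].
#' @param annotations feature annotation data.frame (name, class, genus,
#'   family, phylum); optional.
#' @param rMin minimum correlation magnitude (in (0, 1\]); the headline runs
#'   use 0.4, or 0.6 for small cohorts.
#' @param qMax FDR ceiling (default 0.05).
#' @param group provenance tag for the network.
#' @param excludeUnclassified drop the explicit "unclassified" feature
#'   (default TRUE).
#' @param edgeMask optional data.frame (source, target) restricting the kept
#'   edges to an externally produced sparsification.
#' @return A [MicrobialNetwork-class]; empty (with a warning) if nothing
#'   survives.
#' @export
thresholdNetwork <- function(result, annotations = NULL, rMin, qMax = 0.05,
                             group = "network", excludeUnclassified = TRUE,
                             edgeMask = NULL) {
  stopifnot(is(result, "CorrelationResult"))
  checkRange(rMin, "rMin", 0, 1, lo_open = TRUE)
  checkRange(qMax, "qMax", 0, 1)
  r <- result@r
  q <- result@q
  feats <- rownames(r)
  if (excludeUnclassified) {
    drop <- feats == "unclassified"
    if (!is.null(annotations) && "class" %in% names(annotations)) {
      drop <- drop | annotations$class[match(feats, annotations$name)] %in%
        "unclassified"
    }
    keep <- !drop
    r <- r[keep, keep, drop = FALSE]
    q <- q[keep, keep, drop = FALSE]
    feats <- feats[keep]
  }
  sel <- which(upper.tri(r) & !is.na(r) & abs(r) >= rMin & q <= qMax,
    arr.ind = TRUE)
  edges <- data.frame(
    source = feats[sel[, 1L]], target = feats[sel[, 2L]],
    r = r[sel], p = result@p[cbind(
      match(feats[sel[, 1L]], rownames(result@p)),
      match(feats[sel[, 2L]], rownames(result@p))
    )],
    q = q[sel], stringsAsFactors = FALSE
  )
  if (!is.null(edgeMask)) {
    mask <- edgeKey(edgeMask$source, edgeMask$target)
    edges <- edges[edgeKey(edges$source, edges$target) %in% mask, ,
      drop = FALSE
    ]
  }
  if (nrow(edges) == 0L) {
    warning("no edge passed the thresholds; returning an empty network",
      call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(MicrobialNetwork(g, group = group))
  }
  edges$sign <- ifelse(edges$r < 0, "negative", "positive")
  nodes <- sort(unique(c(edges$source, edges$target)))
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
    m <- match(nodes, ann$name)
    for (col in c("class", "genus", "family", "phylum")) {
      if (col %in% names(ann)) vdf[[col]] <- ann[[col]][m]
    }
    if ("class" %in% names(vdf)) {
      vdf$class[is.na(vdf$class)] <- "unclassified"
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  MicrobialNetwork(g, group = group)
}
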