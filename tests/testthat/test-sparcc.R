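# Basis-correlation estimator, shuffled pseudo p-values, thresholding.

# zero-free count fixture with mild structure, used by the exact invariants
countsFixture <- function(D = 5, n = 30, seed = 4) {
  spec <- CohortSpec(makeTaxaSpec(D),
    nControl = n, nCase = 2,
    depth = 1e5, seed = seed
  )
  x <- abundances(generateCohort(spec)$control)
  x[x == 0] <- 1
  x
}

test_that("degenerate inputs are rejected", {
  x <- countsFixture(5, 30)
  expect_error(estimateBasisCorrelations(x[1:3, ]), "at least 4 features")
  expect_error(estimateBasisCorrelations(x[, 1:2]), "at least 3 samples")
})

test_that("correlation matrix is symmetric with unit diagonal in [-1, 1]", {
  r <- estimateBasisCorrelations(countsFixture(12, 40))
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_equal(unname(diag(r)), rep(1, 12))
  expect_true(all(abs(r) <= 1))
})

test_that("rescaling one sample's counts leaves correlations unchanged", {
  # fractions are identical after closure, so r must match exactly
  x <- countsFixture(8, 25)
  y <- x
  y[, 3] <- y[, 3] * 7
  expect_equal(
    estimateBasisCorrelations(x, exclusionThreshold = 1),
    estimateBasisCorrelations(y, exclusionThreshold = 1),
    tolerance = 1e-12
  )
  expect_equal(
    estimateBasisCorrelations(x),
    estimateBasisCorrelations(y),
    tolerance = 1e-12
  )
})

test_that("no-exclusion output equals the closed-form linear system", {
  # independent direct implementation of the single-pass solution
  x <- countsFixture(5, 30)
  f <- sweep(x, 2, colSums(x), "/")
  lf <- log(f)
  D <- nrow(x)
  t_mat <- matrix(0, D, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i != j) t_mat[i, j] <- var(lf[i, ] - lf[j, ])
    }
  }
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  w <- solve(M, rowSums(t_mat))
  r_direct <- matrix(1, D, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i != j) {
        r_direct[i, j] <- (w[i] + w[j] - t_mat[i, j]) /
          (2 * sqrt(w[i] * w[j]))
      }
    }
  }
  r_direct <- pmin(pmax(r_direct, -1), 1)
  dimnames(r_direct) <- dimnames(x)[c(1, 1)]
  r_pkg <- estimateBasisCorrelations(x, exclusionThreshold = 1)
  expect_equal(r_pkg, r_direct, tolerance = 1e-12)
})

test_that("basis correlations beat naive Pearson-on-fractions for bias", {
  # 40 independent taxa: closure biases Pearson-on-fractions negative; the
  # basis estimator should centre nearer zero
  spec <- CohortSpec(makeTaxaSpec(40),
    nControl = 300, nCase = 2,
    depth = 1e5, seed = 8
  )
  x <- abundances(generateCohort(spec)$control)
  r <- suppressWarnings(estimateBasisCorrelations(x))
  f <- sweep(x + (x == 0), 2, colSums(x + (x == 0)), "/")
  pear <- cor(t(f))
  off <- upper.tri(r)
  expect_lt(
    abs(mean(r[off], na.rm = TRUE)),
    abs(mean(pear[off]))
  )
  expect_lt(mean(pear[off]), 0) # sanity: the naive estimate is biased negative
})

test_that("pseudo p-values follow the add-one estimator against the archive", {
  x <- countsFixture(10, 30)
  res <- shuffledPseudoPvalues(x, nShuffles = 40, seed = 9)
  expect_length(shuffledArchive(res), 40)
  r <- correlations(res)
  p <- pseudoPValues(res)
  # recompute p for a few pairs straight from the archive
  arch <- shuffledArchive(res)
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    i <- pair[1]
    j <- pair[2]
    k <- sum(vapply(arch, function(m) abs(m[i, j]) >= abs(r[i, j]), logical(1)))
    expect_equal(p[i, j], (1 + k) / (1 + 40))
  }
  # a pair beating every shuffle gets the floor 1/(n+1)
  expect_gte(min(p[upper.tri(p)]), 1 / 41)
  # symmetric matrices
  expect_lt(max(abs(p - t(p))), 1e-12)
  expect_lt(max(abs(adjustedPValues(res) - t(adjustedPValues(res))),
    na.rm = TRUE
  ), 1e-12)
  # determinism in the seed
  res2 <- shuffledPseudoPvalues(x, nShuffles = 40, seed = 9)
  expect_identical(pseudoPValues(res2), p)
})

test_that("q-values match the textbook BH step-up over the upper triangle", {
  x <- countsFixture(9, 25, seed = 13)
  res <- shuffledPseudoPvalues(x, nShuffles = 30, seed = 2)
  ut <- upper.tri(correlations(res))
  expect_equal(
    adjustedPValues(res)[ut],
    bhTextbook(pseudoPValues(res)[ut])
  )
})

test_that("thresholding applies |r| and q as a conjunction", {
  feats <- c("A", "B", "C", "D")
  r <- diag(1, 4)
  p <- q <- matrix(1, 4, 4)
  diag(p) <- diag(q) <- 0
  r[1, 2] <- r[2, 1] <- 0.7
  q[1, 2] <- q[2, 1] <- 0.01
  r[3, 4] <- r[4, 3] <- -0.7
  q[3, 4] <- q[4, 3] <- 0.2 # fails q
  r[1, 3] <- r[3, 1] <- 0.3 # fails rMin
  q[1, 3] <- q[3, 1] <- 0.001
  dimnames(r) <- dimnames(p) <- dimnames(q) <- list(feats, feats)
  res <- new("CorrelationResult",
    r = r, p = p, q = q, shuffled = list(),
    params = list(nShuffles = 0L)
  )
  ann <- data.frame(
    name = feats, class = "bacteria", genus = feats,
    family = feats, phylum = "Firmicutes"
  )
  net <- thresholdNetwork(res, ann, rMin = 0.4, qMax = 0.05)
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$source, e$target), c("A", "B"))
  expect_identical(e$sign, "positive")
  # nodes with no surviving edge are dropped
  expect_setequal(networkNodes(net)$name, c("A", "B"))
  # nothing above a harsher rMin: empty network with a warning
  expect_warning(
    empty <- thresholdNetwork(res, ann, rMin = 0.9),
    "empty network"
  )
  expect_identical(nrow(networkEdges(empty)), 0L)
})

test_that("the unclassified aggregate feature is excluded by default", {
  feats <- c("A", "B", "unclassified")
  r <- diag(1, 3)
  r[1, 3] <- r[3, 1] <- 0.9
  r[1, 2] <- r[2, 1] <- 0.8
  p <- q <- matrix(0.001, 3, 3)
  diag(p) <- diag(q) <- 0
  dimnames(r) <- dimnames(p) <- dimnames(q) <- list(feats, feats)
  res <- new("CorrelationResult",
    r = r, p = p, q = q, shuffled = list(),
    params = list(nShuffles = 0L)
  )
  net <- thresholdNetwork(res, rMin = 0.4)
  expect_false("unclassified" %in% networkNodes(net)$name)
  net2 <- thresholdNetwork(res, rMin = 0.4, excludeUnclassified = FALSE)
  expect_true("unclassified" %in% networkNodes(net2)$name)
})

test_that("an edge mask restricts the network to the listed pairs", {
  feats <- c("A", "B", "C", "D")
  r <- diag(1, 4)
  r[1, 2] <- r[2, 1] <- 0.8
  r[3, 4] <- r[4, 3] <- 0.8
  p <- q <- matrix(0.001, 4, 4)
  diag(p) <- diag(q) <- 0
  dimnames(r) <- dimnames(p) <- dimnames(q) <- list(feats, feats)
  res <- new("CorrelationResult",
    r = r, p = p, q = q, shuffled = list(),
    params = list(nShuffles = 0L)
  )
  net <- thresholdNetwork(res,
    rMin = 0.4,
    edgeMask = data.frame(source = "B", target = "A")
  )
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$source, e$target), c("A", "B"))
})
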