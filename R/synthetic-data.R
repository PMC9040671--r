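## Synthetic compositional cohorts and annotated toy graphs.
##
## The generator follows a standard compositional benchmark: latent (basis)
## abundances are multivariate log-normal with a planted correlation matrix,
## closed to fractions per sample, then read counts are drawn from a
## multinomial at the requested depth. Data generated this way approximately
## satisfy the sparse-correlation assumptions the basis-correlation estimator
## relies on.

#' Build a labelled TaxaSpec deterministically
#'
#' Convenience constructor: names are B1..Bn / P1.. / E1.. by class, phyla
#' cycle through the four dominant gut phyla for bacteria, and families group
#' consecutive taxa in threes. All label assignment is deterministic in taxon
#' order so fixtures are stable.
#'
#' @param nBacteria,nPhage,nEukVirus counts per class.
#' @param logMean,logSd log-normal basis parameters (recycled).
#' @return A [TaxaSpec-class].
#' @export
#' @examples
#' makeTaxaSpec(6, 2, 1)
makeTaxaSpec <- function(nBacteria, nPhage = 0L, nEukVirus = 0L,
                         logMean = 0, logSd = 1) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria")
  mk <- function(prefix, n, class, phylum) {
    if (n == 0L) {
      return(NULL)
    }
    name <- paste0(prefix, seq_len(n))
    data.frame(
      name = name, class = class, genus = name,
      family = paste0(prefix, "fam", (seq_len(n) - 1L) %/% 3L + 1L),
      phylum = phylum, stringsAsFactors = FALSE
    )
  }
  taxa <- rbind(
    mk("B", nBacteria, "bacteria",
      phyla[(seq_len(nBacteria) - 1L) %% length(phyla) + 1L]),
    mk("P", nPhage, "phage", NA_character_),
    mk("E", nEukVirus, "eukaryotic_virus", NA_character_)
  )
  TaxaSpec(taxa, logMean = logMean, logSd = logSd)
}

# One arm: multivariate log-normal basis -> fractions -> multinomial counts.
generateArm <- function(taxaSpec, corStructure, n, depth, sampleNames) {
  nm <- taxaSpec@taxa$name
  D <- length(nm)
  R <- corStructureMatrix(corStructure@taxa, corStructure@pairs)
  S <- diag(taxaSpec@logSd, D)
  Sigma <- S %*% R %*% S
  X <- MASS::mvrnorm(n, mu = taxaSpec@logMean, Sigma = Sigma)
  basis <- t(exp(X)) # taxa x samples
  frac <- sweep(basis, 2L, colSums(basis), "/")
  counts <- vapply(
    seq_len(n),
    function(j) stats::rmultinom(1L, size = depth, prob = frac[, j])[, 1L],
    numeric(D)
  )
  dimnames(counts) <- list(nm, sampleNames)
  AbundanceMatrix(counts, "count", annotations = taxaSpec@taxa)
}

#' Generate a paired case/control synthetic cohort
#'
#' Draws both arms of a [CohortSpec-class]: per arm, a multivariate-normal
#' log-basis with the arm's planted correlation matrix is exponentiated,
#' closed to per-sample fractions and sampled as multinomial counts at the
#' arm's depth. Fully reproducible from `spec@seed`.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements `control` and `case`, each an
#'   [AbundanceMatrix-class] of counts (taxa x samples).
#' @export
#' @examples
#' spec <- CohortSpec(makeTaxaSpec(8), nControl = 5, nCase = 5,
#'   depth = 1e4, seed = 7)
#' cohort <- generateCohort(spec)
#' colSums(abundances(cohort$control)) # every column sums to the depth
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    control <- generateArm(
      spec@taxa, spec@controlCor, spec@nControl, spec@depthControl,
      sprintf("ctrl_%02d", seq_len(spec@nControl))
    )
    case <- generateArm(
      spec@taxa, spec@caseCor, spec@nCase, spec@depthCase,
      sprintf("case_%02d", seq_len(spec@nCase))
    )
    list(control = control, case = case)
  })
}

#' Convert a count or RPK abundance matrix to relative abundances
#'
#' @param x an [AbundanceMatrix-class].
#' @return An [AbundanceMatrix-class] of kind `"relative"` whose columns sum
#'   to 1.
#' @export
relativeAbundance <- function(x) {
  stopifnot(is(x, "AbundanceMatrix"))
  v <- x@values
  cs <- colSums(v)
  zero <- cs == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
      paste(colnames(v)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  AbundanceMatrix(sweep(v, 2L, cs, "/"), "relative",
    annotations = x@annotations)
}

#' Generate an annotated toy graph
#'
#' Small deterministic or seeded graph fixtures for topology work:
#' \describe{
#'   \item{two_cliques_bridged}{two k-cliques joined by a single bridge edge
#'     (`params$k`).}
#'   \item{barbell_cliques}{two k-cliques joined by a path of
#'     `params$path_n` intermediate nodes.}
#'   \item{ring_with_shortcut}{a cycle of `params$n` bacteria, plus (when
#'     `params$virus = TRUE`, the default) one virus node adjacent to ring
#'     positions `params$virus_at` (default positions 1 and n/2 + 1).}
#'   \item{power_law}{`params$n` nodes with degrees sampled from
#'     P(d) proportional to d^-gamma (`params$gamma`, default 2.5); errors if the
#'     sampled degree sequence is not realizable as a simple graph.}
#'   \item{random_gnm}{G(n, m) uniform over simple graphs
#'     (`params$n`, `params$m`).}
#' }
#' Node classes are assigned deterministically from node order via
#' `params$classes` (recycled; default all `"bacteria"`, except the
#' ring-with-shortcut virus node).
#'
#' @param kind one of the five kinds above.
#' @param params list of kind-specific parameters.
#' @param seed integer seed (used by the random kinds).
#' @return A [MicrobialNetwork-class].
#' @export
#' @examples
#' generateToyGraph("two_cliques_bridged", list(k = 4))
generateToyGraph <- function(kind = c(
                               "two_cliques_bridged", "barbell_cliques",
                               "ring_with_shortcut", "power_law", "random_gnm"
                             ),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  g <- switch(kind,
    two_cliques_bridged = {
      k <- params$k %||% 4L
      stopifnot(k >= 1L)
      g1 <- igraph::make_full_graph(k)
      g2 <- igraph::make_full_graph(k)
      g <- igraph::disjoint_union(g1, g2)
      if (k >= 1L) g <- igraph::add_edges(g, c(1L, k + 1L))
      igraph::V(g)$name <- paste0("n", seq_len(2L * k))
      g
    },
    barbell_cliques = {
      k <- params$k %||% 4L
      pn <- params$path_n %||% 1L
      stopifnot(k >= 1L, pn >= 0L)
      g <- igraph::disjoint_union(
        igraph::make_full_graph(k), igraph::make_full_graph(k)
      )
      if (pn > 0L) {
        g <- igraph::add_vertices(g, pn)
        chain <- c(1L, 2L * k + seq_len(pn), k + 1L)
        g <- igraph::add_edges(g, rep(chain, each = 2L)[-c(1L, 2L * (pn + 2L))])
      } else {
        g <- igraph::add_edges(g, c(1L, k + 1L))
      }
      igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
      g
    },
    ring_with_shortcut = {
      n <- params$n %||% 8L
      stopifnot(n >= 3L)
      g <- igraph::make_ring(n)
      igraph::V(g)$name <- paste0("b", seq_len(n))
      igraph::V(g)$class <- "bacteria"
      if (params$virus %||% TRUE) {
        at <- params$virus_at %||% c(1L, n %/% 2L + 1L)
        g <- igraph::add_vertices(g, 1L, name = "v1", class = "phage")
        g <- igraph::add_edges(g, as.vector(rbind(n + 1L, at)))
      }
      g
    },
    power_law = {
      n <- params$n %||% 30L
      gamma <- params$gamma %||% 2.5
      stopifnot(n >= 2L)
      degs <- withSeed(seed, {
        dmax <- max(2L, floor(sqrt(n)))
        p <- (seq_len(dmax))^(-gamma)
        d <- sample(seq_len(dmax), n, replace = TRUE, prob = p)
        if (sum(d) %% 2L == 1L) d[which.min(d)] <- d[which.min(d)] + 1L
        d
      })
      if (!igraph::is_graphical(degs)) {
        stop("sampled power-law degree sequence is not realizable as a simple graph",
          call. = FALSE
        )
      }
      g <- withSeed(seed + 1L, igraph::sample_degseq(degs, method = "fast.heur.simple"))
      igraph::V(g)$name <- paste0("n", seq_len(n))
      g
    },
    random_gnm = {
      n <- params$n %||% 10L
      m <- params$m %||% 15L
      if (m > choose(n, 2L)) {
        stop("m exceeds the number of possible edges C(n, 2)", call. = FALSE)
      }
      g <- withSeed(seed, igraph::sample_gnm(n, m))
      igraph::V(g)$name <- paste0("n", seq_len(n))
      g
    }
  )
  if (!is.null(params$classes)) {
    igraph::V(g)$class <- rep_len(params$classes, igraph::vcount(g))
  }
  if (!is.null(params$phyla)) {
    igraph::V(g)$phylum <- rep_len(params$phyla, igraph::vcount(g))
  }
  MicrobialNetwork(g, group = kind)
}

#' Planted pairs for an equicorrelated module
#'
#' Enumerates all pairs of `taxa` at a common target basis correlation `r`
#' (an equicorrelated block, positive semi-definite for r > -1/(k-1)).
#'
#' @param taxa character vector of module members (>= 2).
#' @param r common target correlation.
#' @return data.frame (taxon_i, taxon_j, r) for [CorrelationStructure()].
#' @export
plantedPairs <- function(taxa, r) {
  stopifnot(length(taxa) >= 2L)
  cmb <- t(utils::combn(taxa, 2L))
  data.frame(
    taxon_i = cmb[, 1L], taxon_j = cmb[, 2L], r = r,
    stringsAsFactors = FALSE
  )
}

#' Planted pairs from a single-factor loading structure
#'
#' Builds the pair list of the one-factor correlation model
#' r_ij = loading_i * loading_j, which is positive semi-definite by
#' construction for loadings in \[-1, 1\]. Taxa with positive loadings
#' correlate positively among themselves and negatively with
#' negative-loading taxa - a compact way to plant mixed-sign structure.
#'
#' @param loadings named numeric vector (names = taxa, values in \[-1, 1\]).
#' @return data.frame (taxon_i, taxon_j, r) for [CorrelationStructure()].
#' @export
factorCorrelationPairs <- function(loadings) {
  stopifnot(length(loadings) >= 2L, !is.null(names(loadings)),
    all(abs(loadings) <= 1))
  cmb <- t(utils::combn(names(loadings), 2L))
  data.frame(
    taxon_i = cmb[, 1L], taxon_j = cmb[, 2L],
    r = loadings[cmb[, 1L]] * loadings[cmb[, 2L]],
    stringsAsFactors = FALSE, row.names = NULL
  )
}
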