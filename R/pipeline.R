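## End-to-end orchestration of the analysis stages.

# deterministic stage seeds derived from the root seed (kept in 32-bit range)
stageSeed <- function(seed, offset) {
  (as.integer(seed) + 1009L * offset) %% 2147483647L
}

#' Run the full co-occurrence analysis pipeline
#'
#' Chains the stages on a paired case/control cohort: relative-abundance
#' closure, prevalence filter, basis correlations with shuffled pseudo
#' p-values, network thresholding, disease- and healthy-specific
#' differential networks, node/graph metrics with null-model tests,
#' key-virus selection and link-sign enrichment. Inputs are either a
#' [CohortSpec-class] (synthetic cohort; generated internally) or a pair of
#' count [AbundanceMatrix-class] objects. Every stage derives its seed from
#' `config$seed`, so re-running with the same inputs reproduces the bundle
#' bit for bit. Stage failures abort with the stage name; completed stages
#' are preserved in the error's `partial` attribute.
#'
#' @param config a [pipelineConfig()] list.
#' @param cohortSpec optional [CohortSpec-class] for synthetic input.
#' @param caseCounts,controlCounts count matrices when not simulating
#'   (`controlCounts` may be NULL for a single-group run, which skips the
#'   differential stages with a notice).
#' @param annotations feature annotation table (defaults to the abundance
#'   matrices' own).
#' @param verbose print per-stage timing messages (default FALSE).
#' @return A named list bundle: `abundance`, `correlation`, `networks`,
#'   `differential`, `metrics`, `nullTests`, `keyViruses`, `enrichment`,
#'   `notices`, `provenance`.
#' @export
runPipeline <- function(config = pipelineConfig(), cohortSpec = NULL,
                        caseCounts = NULL, controlCounts = NULL,
                        annotations = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  bundle <- list(notices = character())
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
        conditionMessage(e)))
      attr(err, "partial") <- bundle
      stop(err)
    })
    say("stage %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  inputs <- stage("input", {
    if (!is.null(cohortSpec)) {
      cohort <- generateCohort(cohortSpec)
      list(case = cohort$case, control = cohort$control)
    } else {
      if (is.null(caseCounts)) {
        stop("either cohortSpec or caseCounts must be supplied")
      }
      list(case = caseCounts, control = controlCounts)
    }
  })
  ann <- annotations %||% featureData(inputs$case)

  filtered <- stage("profile", {
    lapply(Filter(Negate(is.null), inputs), function(x) {
      prevalenceFilter(x, config$prevalence)
    })
  })
  bundle$abundance <- filtered

  correlation <- stage("correlate", {
    res <- list()
    offs <- 1L
    for (arm in names(filtered)) {
      res[[arm]] <- shuffledPseudoPvalues(
        filtered[[arm]],
        nShuffles = config$nShuffles,
        seed = stageSeed(config$seed, offs)
      )
      offs <- offs + 1L
    }
    res
  })
  bundle$correlation <- correlation

  networks <- stage("threshold", {
    out <- list()
    for (arm in names(correlation)) {
      out[[arm]] <- suppressWarnings(thresholdNetwork(
        correlation[[arm]], annotations = ann,
        rMin = config$rMin, qMax = config$qMax, group = arm
      ))
    }
    out
  })
  bundle$networks <- networks

  single_group <- is.null(inputs$control)
  if (single_group) {
    bundle["differential"] <- list(NULL)
    bundle$notices <- c(bundle$notices,
      "single-group input: differential-network stage skipped")
  } else {
    bundle$differential <- stage("diffnet", {
      list(
        disease = buildDiseaseSpecificNetwork(
          networks$case, correlation$case,
          networks$control, correlation$control,
          quantile = config$diffQuantile
        ),
        healthy = buildDiseaseSpecificNetwork(
          networks$control, correlation$control,
          networks$case, correlation$case,
          quantile = config$diffQuantile
        )
      )
    })
  }

  focal <- if (single_group) {
    networks$case
  } else {
    bundle$differential$disease$network
  }

  bundle["metrics"] <- list(stage("metrics", {
    if (igraph::vcount(focal@graph) >= 2L) {
      list(node = nodeMetrics(focal), graph = graphMetrics(focal))
    } else {
      bundle$notices <- c(bundle$notices,
        "focal network too small for metrics")
      NULL
    }
  }))

  bundle["nullTests"] <- list(stage("nulls", {
    g <- focal@graph
    if (igraph::vcount(g) >= 4L && igraph::ecount(g) >= 3L) {
      metrics <- c("modularity", "scale_free", "apl")
      out <- lapply(seq_along(metrics), function(i) {
        nullModelTest(g, metrics[i],
          nRandom = config$nNullGraphs,
          seed = stageSeed(config$seed, 10L + i)
        )
      })
      names(out) <- metrics
      out
    } else {
      NULL
    }
  }))

  bundle["keyViruses"] <- list(stage("keyvirus", {
    classes <- igraph::V(focal@graph)$class
    if (sum(classes == "bacteria") >= 2L) {
      keyVirusSelection(focal)
    } else {
      NULL
    }
  }))

  bundle["enrichment"] <- list(stage("enrich", {
    et <- networkEdges(focal)
    classes <- igraph::V(focal@graph)$class
    nm <- igraph::V(focal@graph)$name
    has_bv <- nrow(et) > 0 && any(
      (classes[match(et$source, nm)] == "bacteria" &
        classes[match(et$target, nm)] %in% .VIRUS_CLASSES) |
        (classes[match(et$target, nm)] == "bacteria" &
          classes[match(et$source, nm)] %in% .VIRUS_CLASSES)
    )
    if (has_bv) {
      linkSignEnrichment(focal,
        nPerm = config$nPerm,
        seed = stageSeed(config$seed, 20L)
      )
    } else {
      NULL
    }
  }))
  if (is.null(bundle$enrichment)) {
    bundle$notices <- c(bundle$notices,
      "no bacteria-virus links: enrichment stage skipped")
  }

  bundle$provenance <- list(config = config, generatedBy = "runPipeline")
  bundle
}
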