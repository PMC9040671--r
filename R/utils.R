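# Internal helpers shared across modules.

# Controlled vocabulary for node/feature classes.
.CLASS_LEVELS <- c("bacteria", "phage", "eukaryotic_virus", "unclassified")
.VIRUS_CLASSES <- c("phage", "eukaryotic_virus")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions do
#' not perturb the global random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Canonical key for an undirected edge; order-independent.
edgeKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Assert a scalar lies in a range; used by config/constructor validation.
checkRange <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  }
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "'%s' = %g is outside %s%g, %g%s", name, x,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

# Data-frame of edges of an igraph with endpoint attributes attached.
edgeTable <- function(g) {
  if (igraph::ecount(g) == 0L) {
    return(data.frame(
      source = character(), target = character(),
      sign = character(), stringsAsFactors = FALSE
    ))
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(
    source = ends[, 1L], target = ends[, 2L],
    stringsAsFactors = FALSE
  )
  for (at in igraph::edge_attr_names(g)) {
    df[[at]] <- igraph::edge_attr(g, at)
  }
  df
}

nodeTable <- function(g) {
  df <- data.frame(name = igraph::V(g)$name, stringsAsFactors = FALSE)
  for (at in setdiff(igraph::vertex_attr_names(g), "name")) {
    df[[at]] <- igraph::vertex_attr(g, at)
  }
  df
}
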