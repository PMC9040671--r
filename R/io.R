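## Tab-separated and GraphML readers/writers plus configuration handling.
##
## Dialect: UTF-8 TSV; '#'-prefixed comment lines carry provenance (the
## abundance `kind` tag and, for pipeline outputs, the serialized config).

# read a TSV skipping '#' comment lines, remembering them
readTsvWithComments <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  df <- utils::read.delim(
    text = paste(lines[!is_comment], collapse = "\n"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  attr(df, "comments") <- lines[is_comment]
  df
}

#' Write an abundance matrix as TSV
#'
#' Features as rows, a `feature` id column, header row of sample ids, and a
#' `# kind=` provenance comment line.
#'
#' @param x an [AbundanceMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAbundanceTsv <- function(x, path) {
  stopifnot(is(x, "AbundanceMatrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# kind=", x@kind), con)
  df <- data.frame(feature = rownames(x@values), x@values,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV written by [writeAbundanceTsv()] (or matching its layout:
#'   a `feature` column plus numeric sample columns, with an optional
#'   `# kind=` comment).
#' @param annotations optional annotation table for the features.
#' @return An [AbundanceMatrix-class].
#' @export
readAbundanceTsv <- function(path, annotations = NULL) {
  df <- readTsvWithComments(path)
  comments <- attr(df, "comments")
  kind <- "count"
  km <- grep("^#\\s*kind=", comments, value = TRUE)
  if (length(km)) kind <- sub("^#\\s*kind=", "", km[1L])
  if (!"feature" %in% names(df)) {
    stop("abundance TSV must have a 'feature' column: ", path, call. = FALSE)
  }
  dup <- duplicated(df$feature)
  if (any(dup)) {
    stop("duplicate feature id(s) at data row(s) ",
      paste(which(dup), collapse = ", "), " of ", path,
      call. = FALSE
    )
  }
  m <- as.matrix(df[, setdiff(names(df), "feature"), drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(
      df[, setdiff(names(df), "feature"), drop = FALSE],
      is.numeric, logical(1)
    ))
    stop("non-numeric abundance column(s): ",
      paste(names(bad), collapse = ", "), " in ", path, call. = FALSE)
  }
  rownames(m) <- df$feature
  AbundanceMatrix(m, kind = kind, annotations = annotations)
}

#' Write / read a feature annotation table
#'
#' Columns: name, class, genus, family, phylum.
#'
#' @param annotations data.frame of annotations.
#' @param path TSV file.
#' @return The path (write) or the annotation data.frame (read).
#' @export
writeAnnotationTsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeAnnotationTsv
#' @export
readAnnotationTsv <- function(path) {
  df <- readTsvWithComments(path)
  need <- c("name", "class", "genus", "family", "phylum")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col)) {
    stop("annotation TSV lacks column(s): ",
      paste(missing_col, collapse = ", "), " in ", path, call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate feature name(s) in ", path, call. = FALSE)
  }
  df
}

#' Write / read a network edge list as TSV
#'
#' Columns source, target plus any edge attributes (r, p, q, sign,
#' category, ...) and a `group` column with the network's provenance tag.
#' Reading rejects duplicated undirected edges, naming the offending data
#' row.
#'
#' @param x a [MicrobialNetwork-class] (write) .
#' @param path TSV file.
#' @param annotations optional node annotation table used when rebuilding
#'   the network on read.
#' @return The path (write) or a [MicrobialNetwork-class] (read).
#' @export
writeEdgeListTsv <- function(x, path) {
  stopifnot(is(x, "MicrobialNetwork"))
  et <- edgeTable(x@graph)
  et$group <- x@group
  utils::write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEdgeListTsv
#' @export
readEdgeListTsv <- function(path, annotations = NULL) {
  df <- readTsvWithComments(path)
  if (!all(c("source", "target") %in% names(df))) {
    stop("edge list needs 'source' and 'target' columns: ", path,
      call. = FALSE)
  }
  key <- edgeKey(df$source, df$target)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate undirected edge(s) at data row(s) ",
      paste(which(dup), collapse = ", "), " of ", path,
      call. = FALSE
    )
  }
  if (any(df$source == df$target)) {
    stop("self-loop edge(s) in ", path, call. = FALSE)
  }
  group <- if ("group" %in% names(df)) df$group[1L] else "network"
  nodes <- sort(unique(c(df$source, df$target)))
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    m <- match(nodes, annotations$name)
    for (col in c("class", "genus", "family", "phylum")) {
      if (col %in% names(annotations)) vdf[[col]] <- annotations[[col]][m]
    }
  }
  edge_cols <- setdiff(names(df), "group")
  g <- igraph::graph_from_data_frame(df[, edge_cols, drop = FALSE],
    directed = FALSE, vertices = vdf)
  MicrobialNetwork(g, group = group)
}

#' Export a network as GraphML
#'
#' Attribute-rich exchange format: node class/genus/family/phylum and edge
#' r/p/q/sign attributes are preserved.
#'
#' @param x a [MicrobialNetwork-class].
#' @param path output `.graphml` file.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphML <- function(x, path) {
  stopifnot(is(x, "MicrobialNetwork"))
  g <- x@graph
  # GraphML writers reject NA attribute values; blank them out
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v) && anyNA(v)) {
      igraph::vertex_attr(g, at) <- ifelse(is.na(v), "", v)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Pipeline configuration with the study's default thresholds
#'
#' Bundles every tunable of the pipeline: correlation threshold `rMin`
#' (0.4 by default; 0.6 is the small-cohort setting), FDR ceiling `qMax`,
#' prevalence floor, shuffle / permutation / null-graph counts, the
#' differential-network quantile, the core-network recurrence minimum and
#' the root seed. All values are range-checked.
#'
#' @param rMin,qMax correlation and FDR thresholds for network edges.
#' @param prevalence minimum fraction of samples a feature must appear in.
#' @param nShuffles shuffled matrices for pseudo p-values.
#' @param diffQuantile differential-network null quantile.
#' @param nPerm link-sign permutation draws.
#' @param nNullGraphs random graphs for null-model tests.
#' @param coreMin core-network recurrence minimum.
#' @param seed root seed; every stage derives its seed from it.
#' @return A validated named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(rMin = 0.4, qMax = 0.05, prevalence = 0.2,
                           nShuffles = 100L, diffQuantile = 0.95,
                           nPerm = 100000L, nNullGraphs = 1000L,
                           coreMin = 4L, seed = 1L) {
  checkRange(rMin, "rMin", 0, 1, lo_open = TRUE)
  checkRange(qMax, "qMax", 0, 1)
  checkRange(prevalence, "prevalence", 0, 1, lo_open = TRUE)
  checkRange(diffQuantile, "diffQuantile", 0, 1, lo_open = TRUE,
    hi_open = TRUE)
  checkRange(nShuffles, "nShuffles", 1, Inf)
  checkRange(nPerm, "nPerm", 1, Inf)
  checkRange(nNullGraphs, "nNullGraphs", 1, Inf)
  checkRange(coreMin, "coreMin", 1, Inf)
  checkRange(seed, "seed", -.Machine$integer.max, .Machine$integer.max)
  structure(
    list(
      rMin = rMin, qMax = qMax, prevalence = prevalence,
      nShuffles = as.integer(nShuffles), diffQuantile = diffQuantile,
      nPerm = as.integer(nPerm), nNullGraphs = as.integer(nNullGraphs),
      coreMin = as.integer(coreMin), seed = as.integer(seed)
    ),
    class = "pipelineConfig"
  )
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' The extension decides the format (`.yaml`/`.yml` or `.json`). Values are
#' validated through [pipelineConfig()] on read, so malformed settings fail
#' immediately.
#'
#' @param config a `pipelineConfig` list.
#' @param path config file path.
#' @return The path (write) or a validated `pipelineConfig` (read).
#' @export
writeConfig <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("config path must end in .yaml/.yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml/.yml or .json", call. = FALSE)
  }
  do.call(pipelineConfig, cfg)
}
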