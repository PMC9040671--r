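## Abundance profiles from read-mapping summaries.
##
## Contig abundance is reads-per-kilobase, a_i = x_i / L_i * 1000; each gene
## on a contig inherits a_i / n_i, treating gene abundance as a proxy for the
## abundance of the organism carrying it. Taxon profiles sum gene abundances
## by annotation and close each sample to 1.

#' Contig and gene abundance from read-mapping summaries
#'
#' Computes reads-per-kilobase contig abundance `a = reads / length * 1000`
#' per sample and distributes it evenly over the genes of the contig
#' (`g = a / n_genes`), yielding a gene x sample RPK matrix.
#'
#' @param mapping data.frame with columns `sample`, `contig_id`, `reads`,
#'   `length`, `n_genes`. `length` and `n_genes` must be consistent within a
#'   contig; contigs absent from a sample are taken as zero reads.
#' @param genes data.frame with columns `gene_id`, `contig_id` (plus any
#'   annotation columns, carried through).
#' @return An [AbundanceMatrix-class] of kind `"rpk"` (genes x samples).
#' @export
contigGeneAbundance <- function(mapping, genes) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need_m <- c("sample", "contig_id", "reads", "length", "n_genes")
  if (!all(need_m %in% names(mapping))) {
    stop("mapping needs columns: ", paste(need_m, collapse = ", "),
      call. = FALSE)
  }
  if (!all(c("gene_id", "contig_id") %in% names(genes))) {
    stop("genes needs columns: gene_id, contig_id", call. = FALSE)
  }
  if (any(mapping$length < 1)) {
    stop("contig lengths must be >= 1 bp", call. = FALSE)
  }
  if (any(mapping$n_genes < 1)) {
    stop("contig gene counts must be >= 1", call. = FALSE)
  }
  if (any(mapping$reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids", call. = FALSE)
  }
  # per-contig invariants across samples
  info <- unique(mapping[, c("contig_id", "length", "n_genes")])
  if (anyDuplicated(info$contig_id)) {
    bad <- info$contig_id[duplicated(info$contig_id)]
    stop("inconsistent length/n_genes for contig(s): ",
      paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(genes$contig_id, info$contig_id)
  if (length(orphan)) {
    stop(
      "genes reference contigs absent from the mapping: ",
      paste(genes$gene_id[genes$contig_id %in% orphan], collapse = ", "),
      call. = FALSE
    )
  }
  samples <- unique(mapping$sample)
  contigs <- info$contig_id
  reads <- matrix(0, length(contigs), length(samples),
    dimnames = list(contigs, samples))
  reads[cbind(
    match(mapping$contig_id, contigs),
    match(mapping$sample, samples)
  )] <- mapping$reads
  a <- reads / info$length * 1000 # contig RPK
  idx <- match(genes$contig_id, contigs)
  g <- a[idx, , drop = FALSE] / info$n_genes[idx]
  rownames(g) <- genes$gene_id
  ann <- genes
  names(ann)[names(ann) == "gene_id"] <- "name"
  for (col in c("class", "genus", "family", "phylum")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  AbundanceMatrix(g, "rpk", annotations = ann)
}

#' Taxon-level relative abundance profile
#'
#' Sums gene abundances by taxon at the requested rank per sample, then
#' closes each sample to 1. Genes without an annotation at the rank are
#' aggregated into an explicit `"unclassified"` feature so closure holds;
#' network stages exclude it by default.
#'
#' @param genes gene-level [AbundanceMatrix-class] (any kind).
#' @param annotations optional annotation data.frame with `name` plus the
#'   rank column; defaults to `featureData(genes)`.
#' @param rank `"genus"`, `"family"` or `"phylum"`.
#' @return An [AbundanceMatrix-class] of kind `"relative"` (taxa x samples).
#' @export
taxonRelativeAbundance <- function(genes, annotations = NULL,
                                   rank = c("genus", "family", "phylum")) {
  rank <- match.arg(rank)
  stopifnot(is(genes, "AbundanceMatrix"))
  ann <- annotations %||% featureData(genes)
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (!rank %in% names(ann)) {
    stop("annotations lack a '", rank, "' column", call. = FALSE)
  }
  lab <- ann[[rank]][match(rownames(genes@values), ann$name)]
  lab[is.na(lab) | lab == ""] <- "unclassified"
  if (all(lab == "unclassified")) {
    stop("no gene carries a '", rank, "' annotation", call. = FALSE)
  }
  v <- rowsum(genes@values, lab)
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
      paste(colnames(v)[cs == 0], collapse = ", "), call. = FALSE)
  }
  rel <- sweep(v, 2L, cs, "/")
  # carry class/family/phylum context where it is unambiguous within a taxon
  gene_lab <- lab
  carry <- function(col) {
    if (!col %in% names(ann)) {
      return(rep(NA_character_, nrow(rel)))
    }
    vals <- ann[[col]][match(rownames(genes@values), ann$name)]
    vapply(rownames(rel), function(tx) {
      u <- unique(vals[gene_lab == tx])
      u <- u[!is.na(u)]
      if (length(u) == 1L) u else NA_character_
    }, character(1))
  }
  out_ann <- data.frame(
    name = rownames(rel),
    class = carry("class"),
    genus = if (rank == "genus") rownames(rel) else NA_character_,
    family = if (rank == "family") rownames(rel) else carry("family"),
    phylum = if (rank == "phylum") rownames(rel) else carry("phylum"),
    stringsAsFactors = FALSE
  )
  out_ann$class[is.na(out_ann$class)] <- "unclassified"
  out_ann$class[out_ann$name == "unclassified"] <- "unclassified"
  AbundanceMatrix(rel, "relative", annotations = out_ann)
}

#' Prevalence filter
#'
#' Removes features with a nonzero value in strictly less than
#' `minFraction` of the samples (the boundary survives: a feature present in
#' exactly `minFraction` of samples is retained). Relative matrices are
#' re-closed after removal so column sums stay 1. The removed feature names
#' are attached as attribute `"removedFeatures"`.
#'
#' @param x an [AbundanceMatrix-class].
#' @param minFraction minimum prevalence in (0, 1], default 0.2.
#' @return The filtered [AbundanceMatrix-class].
#' @export
prevalenceFilter <- function(x, minFraction = 0.2) {
  stopifnot(is(x, "AbundanceMatrix"))
  checkRange(minFraction, "minFraction", 0, 1, lo_open = TRUE)
  v <- x@values
  prev <- rowSums(v > 0)
  keep <- prev >= minFraction * ncol(v) # strict "less than" removal rule
  if (!any(keep)) {
    stop("prevalence filter removed every feature", call. = FALSE)
  }
  out_v <- v[keep, , drop = FALSE]
  if (identical(x@kind, "relative")) {
    cs <- colSums(out_v)
    if (any(cs == 0)) {
      stop("filtering left all-zero sample column(s): ",
        paste(colnames(out_v)[cs == 0], collapse = ", "), call. = FALSE)
    }
    out_v <- sweep(out_v, 2L, cs, "/")
  }
  out <- AbundanceMatrix(out_v, x@kind,
    annotations = x@annotations[keep, , drop = FALSE])
  attr(out, "removedFeatures") <- rownames(v)[!keep]
  out
}
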