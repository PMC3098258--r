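#' Read a gene-phenotype association report
#'
#' Parses a TSV report into an \linkS4class{AnnotationSet}. Column
#' indices are configurable so that both curated-repository style
#' reports (gene and term somewhere among genotype columns) and
#' high-throughput exports reduce to (gene, term) pairs. Rows with a
#' missing gene or term field are skipped and counted. Records are
#' deduplicated on gene x term, which also collapses genotype zygosity:
#' if either a heterozygote or homozygote line shows the phenotype the
#' gene is associated once.
#'
#' @param path TSV file path; lines starting with \code{comment} ignored.
#' @param geneCol,termCol 1-based column indices of the gene and term id.
#' @param source label recorded on each record ("curated",
#'   "highthroughput" or "synthetic").
#' @param header whether the file carries a header line.
#' @param comment comment prefix (default "#").
#' @return an \linkS4class{AnnotationSet}.
#' @export
readAnnotations <- function(path, geneCol = 1L, termCol = 2L,
                            source = c("curated", "highthroughput",
                                       "synthetic"),
                            header = FALSE, comment = "#") {
  source <- match.arg(source)
  if (!file.exists(path)) stop("annotation report not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = header,
                          comment.char = comment, stringsAsFactors = FALSE,
                          quote = "", fill = TRUE,
                          colClasses = "character")
  need <- max(geneCol, termCol)
  if (ncol(df) < need)
    stop("report has ", ncol(df), " columns; need at least ", need)
  gene <- trimws(df[[geneCol]])
  term <- trimws(df[[termCol]])
  ok <- nzchar(gene) & nzchar(term) & !is.na(gene) & !is.na(term)
  nskip <- sum(!ok)
  if (nskip) warning(nskip, " malformed row(s) skipped in ", basename(path))
  annotationSet(gene[ok], term[ok], source, nSkipped = as.integer(nskip))
}

# Construct an AnnotationSet from vectors, deduplicating.
annotationSet <- function(gene, term, source = "synthetic",
                          nSkipped = 0L, nUnmapped = 0L) {
  df <- data.frame(gene = as.character(gene), term = as.character(term),
                   source = rep_len(as.character(source), length(gene)),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$gene, df$term)), , drop = FALSE]
  df <- df[order(df$gene, df$term), , drop = FALSE]
  rownames(df) <- NULL
  new("AnnotationSet", records = df, nSkipped = nSkipped,
      nUnmapped = nUnmapped)
}

#' Merge annotation sets into a single non-redundant edge list
#'
#' Union of records, deduplicated on gene x term (the first-seen source
#' label wins for pairs present in both). Merging is commutative in its
#' gene-term content and idempotent.
#'
#' @param ... \linkS4class{AnnotationSet} objects.
#' @return a merged \linkS4class{AnnotationSet}.
#' @export
mergeAnnotations <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, is, TRUE, "AnnotationSet")))
  df <- do.call(rbind, lapply(sets, records))
  df <- df[order(df$gene, df$term), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene, df$term)), , drop = FALSE]
  rownames(df) <- NULL
  new("AnnotationSet", records = df,
      nSkipped = sum(vapply(sets, function(s) s@nSkipped, 0L)),
      nUnmapped = sum(vapply(sets, function(s) s@nUnmapped, 0L)))
}

#' Names of phenotype terms excluded as uninformative
#'
#' The default exclusion list: terms recording that no abnormality was
#' found (or that a phenotype reverted), which convey no useful
#' association signal.
#'
#' @return character vector of term names.
#' @export
defaultExcludedTermNames <- function() {
  c("no phenotypic analysis",
    "normal phenotype",
    "no abnormal phenotype detected",
    "phenotypic reversion",
    "reversion by mitotic recombination",
    "reversion by viral sequence excision")
}

#' Resolve the default exclusion list against an ontology
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param termNames names to exclude (default
#'   \code{\link{defaultExcludedTermNames}}).
#' @return term accessions whose name matches the list.
#' @export
excludedTermIds <- function(dag, termNames = defaultExcludedTermNames()) {
  dag@terms[dag@termNames[dag@terms] %in% termNames]
}

#' Remove excluded terms from an annotation set
#'
#' Drops every record whose term is in \code{exclude}. Genes whose every
#' record is excluded disappear from the gene universe.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param exclude character vector of term accessions to remove.
#' @return the filtered \linkS4class{AnnotationSet}.
#' @export
filterExcluded <- function(annotations, exclude) {
  df <- records(annotations)
  keep <- !(df$term %in% exclude)
  if (!any(keep) && nrow(df))
    warning("all annotation records were excluded")
  out <- annotations
  out@records <- df[keep, , drop = FALSE]
  rownames(out@records) <- NULL
  out
}

#' Map gene identifiers through a two-column table
#'
#' Translates gene ids via a source-to-target mapping (e.g. repository
#' marker ids to stable gene ids). Genes absent from the table are
#' dropped and counted in \code{nUnmapped}; many-to-one mappings are
#' allowed (records are re-deduplicated after mapping); a source id
#' mapped to several distinct targets is an error.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param map data.frame (or 2-column TSV path) with columns from, to.
#' @return the mapped \linkS4class{AnnotationSet}.
#' @export
mapGeneIds <- function(annotations, map) {
  if (is.character(map) && length(map) == 1L) {
    map <- readTsv(map, header = FALSE)
  }
  stopifnot(ncol(map) >= 2L)
  from <- as.character(map[[1]]); to <- as.character(map[[2]])
  dup <- unique(from[duplicated(from)])
  if (length(dup)) {
    conflict <- dup[vapply(dup, function(d)
      length(unique(to[from == d])) > 1L, TRUE)]
    if (length(conflict))
      stop("conflicting mappings for: ",
           paste(utils::head(conflict, 5), collapse = ", "))
  }
  lut <- stats::setNames(to, from)[!duplicated(from)]
  df <- records(annotations)
  tgt <- lut[df$gene]
  unmapped <- is.na(tgt)
  out <- annotationSet(tgt[!unmapped], df$term[!unmapped],
                       source = df$source[!unmapped])
  out@nSkipped <- annotations@nSkipped
  out@nUnmapped <- annotations@nUnmapped + as.integer(sum(unmapped))
  out
}

#' Write an annotation set as a canonical two-column TSV
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param path output path.
#' @export
writeAnnotations <- function(annotations, path) {
  writeTsv(records(annotations)[, c("gene", "term")], path)
}
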