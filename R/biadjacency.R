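#' Build the weighted gene x phenotype biadjacency matrix at a level
#'
#' For every annotation record (gene i, term t) the term's granularity
#' weight g(t) is added to column j for every level-L ancestor j of t
#' (including t itself when it sits exactly at level L, so that level-L
#' annotations are not discarded). Terms with multiple parents can have
#' several level-L ancestors and then contribute to every qualifying
#' column. Columns are all level-L terms receiving at least one
#' contribution; rows are all genes of the annotation set; both are in
#' lexicographic order.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param dag an \linkS4class{OntologyDAG} with levels and granularity
#'   computed (see \code{\link{computeLevels}},
#'   \code{\link{annotateGranularity}}).
#' @param L target ontology level (>= 1).
#' @param includeSelf should a term exactly at level L count as its own
#'   descendant-or-self? Default TRUE.
#' @return a \linkS4class{WeightedBiadjacency} with \code{kind = "gene"}.
#' @export
buildBiadjacency <- function(annotations, dag, L, includeSelf = TRUE) {
  stopifnot(is(annotations, "AnnotationSet"), is(dag, "OntologyDAG"))
  if (!length(dag@level)) stop("call computeLevels() first")
  if (!length(dag@granularity)) stop("call annotateGranularity() first")
  if (L < 1 || L > max(dag@level))
    stop("level ", L, " outside the ontology's depth (max ",
         max(dag@level), ")")
  df <- records(annotations)
  df <- df[df$term %in% dag@terms, , drop = FALSE]
  if (!nrow(df)) stop("empty annotation set (no terms in the ontology)")
  terms <- unique(df$term)
  ancL <- ancestorsAtLevelMap(dag, terms, L)
  if (!includeSelf)
    ancL <- lapply(stats::setNames(terms, terms), function(t)
      setdiff(ancL[[t]], t))
  nAnc <- lengths(ancL[df$term])
  keep <- nAnc > 0L
  if (!any(keep))
    stop("no annotation reaches level ", L, " of the ontology")
  long <- data.frame(
    object = rep(df$gene[keep], nAnc[keep]),
    column = unlist(ancL[df$term[keep]], use.names = FALSE),
    term = rep(df$term[keep], nAnc[keep]),
    stringsAsFactors = FALSE)
  long$weight <- unname(dag@granularity[long$term])
  genes <- sort(unique(df$gene))
  cols <- sort(unique(long$column))
  B <- matrix(0, length(genes), length(cols),
              dimnames = list(genes, cols))
  idx <- cbind(match(long$object, genes), match(long$column, cols))
  for (r in seq_len(nrow(long)))
    B[idx[r, 1], idx[r, 2]] <- B[idx[r, 1], idx[r, 2]] + long$weight[r]
  long <- long[order(long$object, long$column, long$term), , drop = FALSE]
  rownames(long) <- NULL
  new("WeightedBiadjacency", values = B, level = as.integer(L),
      kind = "gene", triples = long)
}

#' Transpose a weighted biadjacency matrix
#'
#' Swaps rows and columns (values are transposed unchanged) and flips
#' the object kind, so that the same association pipeline run on the
#' transposed matrix yields the phenotype-phenotype network. The raw
#' incidence triples swap their object/column roles accordingly.
#'
#' @param x a \linkS4class{WeightedBiadjacency}.
#' @return the transposed \linkS4class{WeightedBiadjacency}.
#' @export
setMethod("t", "WeightedBiadjacency", function(x) {
  tr <- x@triples
  tr <- data.frame(object = tr$column, column = tr$object, term = tr$term,
                   weight = tr$weight, stringsAsFactors = FALSE)
  tr <- tr[order(tr$object, tr$column, tr$term), , drop = FALSE]
  rownames(tr) <- NULL
  new("WeightedBiadjacency", values = t(x@values), level = x@level,
      kind = if (x@kind == "gene") "phenotype" else "gene",
      triples = tr)
})

#' Export a biadjacency matrix
#'
#' Writes the dense matrix as TSV (header row and id column) or as
#' MatrixMarket coordinate format for sparse consumers.
#'
#' @param B a \linkS4class{WeightedBiadjacency}.
#' @param path output path.
#' @param format "tsv" or "mtx".
#' @export
exportBiadjacency <- function(B, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeMatrixTsv(values(B), path)
  } else {
    Matrix::writeMM(Matrix::Matrix(values(B), sparse = TRUE), path)
  }
  invisible(path)
}
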