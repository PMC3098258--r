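#' @import methods
NULL

#' OntologyDAG: a rooted directed acyclic graph of ontology terms
#'
#' Holds the parsed ontology: one entry per non-obsolete term, its
#' \code{is_a} parent links, and (once computed) the per-term level
#' (shortest-path distance from the root, root's children = level 1),
#' the count of annotated descendant terms \code{nAnnotatedBelow} and the
#' granularity weight derived from it.
#'
#' @slot terms character vector of term accessions (unique).
#' @slot termNames named character, free-text name per term.
#' @slot parents named list; each element a character vector of parent
#'   term accessions (empty for the root).
#' @slot children named list, the reverse of \code{parents}.
#' @slot root the single parentless term.
#' @slot level named integer, shortest-path depth below the root
#'   (root = 0L); length 0 until \code{\link{computeLevels}} is called.
#' @slot nAnnotatedBelow named integer, number of strict descendants
#'   carrying at least one annotation; filled by
#'   \code{\link{annotateGranularity}}.
#' @slot granularity named numeric granularity weight per term.
#' @slot granularityScheme scheme used ("inverse" or "linear"), or NA.
#' @export
setClass("OntologyDAG",
  representation(
    terms = "character",
    termNames = "character",
    parents = "list",
    children = "list",
    root = "character",
    level = "integer",
    nAnnotatedBelow = "integer",
    granularity = "numeric",
    granularityScheme = "character"
  ),
  prototype(
    level = integer(0), nAnnotatedBelow = integer(0),
    granularity = numeric(0), granularityScheme = NA_character_
  )
)

setValidity("OntologyDAG", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@terms))
    msg <- c(msg, "term accessions must be unique")
  if (!identical(sort(names(object@parents)), sort(object@terms)))
    msg <- c(msg, "parents must be keyed by every term")
  allp <- unique(unlist(object@parents, use.names = FALSE))
  if (length(allp) && !all(allp %in% object@terms))
    msg <- c(msg, "parent links must reference existing terms")
  if (length(object@root) != 1L || !object@root %in% object@terms)
    msg <- c(msg, "root must be a single existing term")
  else if (length(object@parents[[object@root]]) != 0L)
    msg <- c(msg, "root must have no parents")
  if (length(object@granularity) && any(object@granularity <= 0))
    msg <- c(msg, "granularity weights must be positive")
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: a deduplicated bipartite gene-term edge list
#'
#' @slot records data.frame with columns \code{gene}, \code{term},
#'   \code{source}; unique on gene x term.
#' @slot nSkipped number of malformed rows skipped at parse time.
#' @slot nUnmapped number of records dropped by ID mapping.
#' @export
setClass("AnnotationSet",
  representation(records = "data.frame", nSkipped = "integer",
                 nUnmapped = "integer"),
  prototype(records = data.frame(gene = character(0), term = character(0),
                                 source = character(0),
                                 stringsAsFactors = FALSE),
            nSkipped = 0L, nUnmapped = 0L)
)

setValidity("AnnotationSet", function(object) {
  r <- object@records
  msg <- character(0)
  if (!all(c("gene", "term", "source") %in% names(r)))
    msg <- c(msg, "records must have gene, term, source columns")
  else {
    if (anyDuplicated(paste(r$gene, r$term)))
      msg <- c(msg, "records must be unique on gene x term")
    if (nrow(r) && (any(!nzchar(r$gene)) || any(!nzchar(r$term))))
      msg <- c(msg, "gene and term ids must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' WeightedBiadjacency: weighted gene x phenotype matrix at one level
#'
#' Rows are objects (genes for the gene-side matrix; level-L terms after
#' transposition), columns are features. \code{values} holds the
#' aggregated weights B[i, j] = sum of granularity weights of the raw
#' annotated terms of object i lying at-or-below column term j. The raw
#' (object, column, raw-term, weight) incidence needed by the association
#' score is kept in \code{triples}.
#'
#' @slot values dense numeric matrix with dimnames.
#' @slot level the ontology level L of the term axis.
#' @slot kind "gene" when rows are genes, "phenotype" when rows are terms.
#' @slot triples data.frame(object, column, term, weight): raw incidence.
#' @export
setClass("WeightedBiadjacency",
  representation(values = "matrix", level = "integer", kind = "character",
                 triples = "data.frame")
)

setValidity("WeightedBiadjacency", function(object) {
  msg <- character(0)
  if (any(object@values < 0)) msg <- c(msg, "entries must be non-negative")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "values must carry row and column names")
  if (!object@kind %in% c("gene", "phenotype"))
    msg <- c(msg, "kind must be 'gene' or 'phenotype'")
  if (length(msg)) msg else TRUE
})

#' AssociationMatrix: symmetric pairwise d scores in [0, 1]
#'
#' @slot values symmetric numeric matrix, zero diagonal.
#' @slot kind "gene" or "phenotype".
#' @slot level ontology level the scores were computed at.
#' @slot perFeature optional long data.frame(a, b, feature, p, q) of
#'   per-feature scores for retained pairs (empty unless requested).
#' @export
setClass("AssociationMatrix",
  representation(values = "matrix", kind = "character", level = "integer",
                 perFeature = "data.frame")
)

setValidity("AssociationMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    msg <- c(msg, "matrix must be symmetric")
  if (any(v < 0 | v > 1)) msg <- c(msg, "d scores must lie in [0, 1]")
  if (nrow(v) && any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})

#' NetworkEdgeList: thresholded undirected weighted network
#'
#' @slot edges data.frame(from, to, weight), canonical from < to order,
#'   no self edges, every weight >= dCutoff.
#' @slot nodes character vector of retained (non-isolated) nodes.
#' @slot dCutoff the threshold applied.
#' @slot kind "gene" or "phenotype".
#' @export
setClass("NetworkEdgeList",
  representation(edges = "data.frame", nodes = "character",
                 dCutoff = "numeric", kind = "character")
)

setValidity("NetworkEdgeList", function(object) {
  e <- object@edges
  msg <- character(0)
  if (!all(c("from", "to", "weight") %in% names(e)))
    msg <- c(msg, "edges must have from, to, weight")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$from >= e$to)) msg <- c(msg, "edges must be in from < to order")
    if (any(e$weight < object@dCutoff))
      msg <- c(msg, "all edge weights must reach dCutoff")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Partition: community labels with modularity
#'
#' @slot labels named integer community index per node (1-based).
#' @slot Q Newman modularity of the partition.
#' @slot method character, how the partition was obtained.
#' @slot refined logical, whether Kernighan-Lin style refinement ran.
#' @export
setClass("Partition",
  representation(labels = "integer", Q = "numeric", method = "character",
                 refined = "logical"),
  prototype(method = "newman-spectral", refined = TRUE)
)

setValidity("Partition", function(object) {
  msg <- character(0)
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by node")
  if (length(object@labels) && any(object@labels < 1L))
    msg <- c(msg, "community indices must be >= 1")
  if (length(object@Q) == 1L && !is.na(object@Q) &&
      (object@Q < -1 || object@Q >= 1 + 1e-9))
    msg <- c(msg, "Q must lie in [-1, 1)")
  if (length(msg)) msg else TRUE
})

#' DegreeProfile: degree-distribution and clustering diagnostics
#'
#' @slot k distinct degree values.
#' @slot Pk empirical probability of each degree.
#' @slot Ck mean local clustering coefficient at each degree.
#' @slot gammaHat minus the slope of the log-log P(k) regression.
#' @slot fitR2 R-squared of that regression.
#' @slot ckSlope slope of the log-log C(k) regression (NA if degenerate).
#' @slot degenerate TRUE when fewer than 3 distinct degrees allowed no fit.
#' @export
setClass("DegreeProfile",
  representation(k = "integer", Pk = "numeric", Ck = "numeric",
                 gammaHat = "numeric", fitR2 = "numeric",
                 ckSlope = "numeric", degenerate = "logical")
)

#' RewiringNull: degree-preserving rewiring null distributions
#'
#' @slot nReps number of null replicates.
#' @slot nullC mean local clustering coefficient per replicate.
#' @slot nullQ spectral modularity per replicate.
#' @slot observedC,observedQ observed statistics.
#' @slot pC,pQ one-sided empirical p-values (fraction of nulls >= observed).
#' @slot nDegreeMatched replicates whose degree multiset matched the
#'   observed network's exactly (verified, not assumed; always nReps).
#' @slot seed RNG seed used.
#' @export
setClass("RewiringNull",
  representation(nReps = "integer", nullC = "numeric", nullQ = "numeric",
                 observedC = "numeric", observedQ = "numeric",
                 pC = "numeric", pQ = "numeric",
                 nDegreeMatched = "integer", seed = "integer")
)

#' CommunityEnrichmentResult: within-community vs resampled control
#'
#' @slot metric one of expr_corr, tissue_corr, ppi_count, go_d, phylo_corr.
#' @slot within pooled within-community pairwise values (or observed count
#'   for ppi_count).
#' @slot control pooled values (or counts) from resampled pseudo-communities.
#' @slot pValue one-sided p (within greater than control).
#' @slot nBoot number of resampling replicates.
#' @slot seed RNG seed used.
#' @export
setClass("CommunityEnrichmentResult",
  representation(metric = "character", within = "numeric",
                 control = "numeric", pValue = "numeric",
                 nBoot = "integer", seed = "integer")
)

setValidity("CommunityEnrichmentResult", function(object) {
  ok <- object@metric %in% c("expr_corr", "tissue_corr", "ppi_count",
                             "go_d", "phylo_corr")
  if (!ok) return("unknown metric")
  if (length(object@pValue) == 1L && !is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    return("p-value must lie in [0, 1]")  # NA = undefined (no overlap)
  TRUE
})

#' ContingencyResult: level-1 term sharing chi-square summary
#'
#' @slot table observed counts (groups x shared-term bins).
#' @slot chiSq chi-square statistic.
#' @slot dof degrees of freedom.
#' @slot p p-value.
#' @slot fracSameWithin fraction of within-community pairs sharing >= 1
#'   level-1 term.
#' @slot fracSameOverall same fraction over all pairs.
#' @export
setClass("ContingencyResult",
  representation(table = "matrix", chiSq = "numeric", dof = "integer",
                 p = "numeric", fracSameWithin = "numeric",
                 fracSameOverall = "numeric")
)

#' OverlapMatrix: community-to-group or community-to-community overlap
#'
#' @slot values numeric matrix (-log10 p or mean overlap fraction).
#' @slot mode "tail_p" or "fraction".
#' @slot N universe size used for the hypergeometric mode.
#' @export
setClass("OverlapMatrix",
  representation(values = "matrix", mode = "character", N = "integer")
)

#' PhenotypeDendrogram: average-linkage tree with bootstrap support
#'
#' @slot hclust the \code{stats::hclust} tree over term columns.
#' @slot clusters list of leaf-label sets, one per internal node.
#' @slot bp bootstrap proportion per internal node (NA until computed).
#' @slot au approximately unbiased support per internal node.
#' @slot nBoot total bootstrap replicates across scales.
#' @slot scales row-resampling scale factors.
#' @slot seed RNG seed.
#' @export
setClass("PhenotypeDendrogram",
  representation(hclust = "ANY", clusters = "list", bp = "numeric",
                 au = "numeric", nBoot = "integer", scales = "numeric",
                 seed = "integer")
)

#' SyntheticConfig: parameters of the synthetic planted-module generator
#'
#' See \code{\link{syntheticConfig}} for field semantics and defaults.
#' @slot params named list of generator parameters.
#' @export
setClass("SyntheticConfig", representation(params = "list"))
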