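#' Accessors and show methods
#'
#' Small accessor generics used across the package's S4 containers.
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors term accessions of an OntologyDAG or the record
#'   terms of an AnnotationSet.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @describeIn accessors gene accessions present in an object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn accessors per-term level map of an OntologyDAG.
#' @export
setGeneric("termLevels", function(x) standardGeneric("termLevels"))

#' @describeIn accessors per-term granularity weights.
#' @export
setGeneric("granularity", function(x) standardGeneric("granularity"))

#' @describeIn accessors annotation records data.frame.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @describeIn accessors numeric matrix payload of a matrix-like object.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @describeIn accessors edge data.frame of a NetworkEdgeList.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @describeIn accessors node names of a network or partition.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @describeIn accessors community labels of a Partition.
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @describeIn accessors modularity Q of a Partition.
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

setMethod("termIds", "OntologyDAG", function(x) x@terms)
setMethod("termIds", "AnnotationSet", function(x) unique(x@records$term))
setMethod("geneIds", "AnnotationSet", function(x) unique(x@records$gene))
setMethod("geneIds", "WeightedBiadjacency", function(x)
  if (x@kind == "gene") rownames(x@values) else colnames(x@values))
setMethod("termLevels", "OntologyDAG", function(x) x@level)
setMethod("granularity", "OntologyDAG", function(x) x@granularity)
setMethod("records", "AnnotationSet", function(x) x@records)
setMethod("values", "WeightedBiadjacency", function(x) x@values)
setMethod("values", "AssociationMatrix", function(x) x@values)
setMethod("values", "OverlapMatrix", function(x) x@values)
setMethod("edges", "NetworkEdgeList", function(x) x@edges)
setMethod("nodeIds", "NetworkEdgeList", function(x) x@nodes)
setMethod("nodeIds", "Partition", function(x) names(x@labels))
setMethod("communityLabels", "Partition", function(x) x@labels)
setMethod("modularityQ", "Partition", function(x) x@Q)

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", length(object@terms), "terms, root",
      object@root, "\n")
  if (length(object@level))
    cat("  levels computed: max level", max(object@level), "\n")
  if (length(object@granularity))
    cat("  granularity scheme:", object@granularityScheme, "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", nrow(object@records), "gene-term records,",
      length(geneIds(object)), "genes,",
      length(termIds(object)), "terms\n")
  if (object@nSkipped) cat("  skipped rows:", object@nSkipped, "\n")
  if (object@nUnmapped) cat("  unmapped records:", object@nUnmapped, "\n")
})

setMethod("show", "WeightedBiadjacency", function(object) {
  cat(sprintf("WeightedBiadjacency (%s rows): %d x %d at level %d\n",
              object@kind, nrow(object@values), ncol(object@values),
              object@level))
})

setMethod("show", "AssociationMatrix", function(object) {
  nz <- sum(object@values[upper.tri(object@values)] > 0)
  cat(sprintf("AssociationMatrix (%s): %d nodes, %d nonzero pairs, level %d\n",
              object@kind, nrow(object@values), nz, object@level))
})

setMethod("show", "NetworkEdgeList", function(object) {
  cat(sprintf("NetworkEdgeList (%s): %d nodes, %d edges, d_cutoff = %g\n",
              object@kind, length(object@nodes), nrow(object@edges),
              object@dCutoff))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d nodes in %d communities, Q = %.4f (%s)\n",
              length(object@labels), length(unique(object@labels)),
              object@Q, object@method))
})

setMethod("show", "DegreeProfile", function(object) {
  if (object@degenerate)
    cat("DegreeProfile: degenerate (too few distinct degrees for a fit)\n")
  else
    cat(sprintf("DegreeProfile: gamma_hat = %.3f (R2 = %.3f) over %d degrees\n",
                object@gammaHat, object@fitR2, length(object@k)))
})

setMethod("show", "RewiringNull", function(object) {
  cat(sprintf(
    "RewiringNull: %d replicates; C = %.4f (p = %.3g), Q = %.4f (p = %.3g)\n",
    object@nReps, object@observedC, object@pC, object@observedQ, object@pQ))
})

setMethod("show", "CommunityEnrichmentResult", function(object) {
  cat(sprintf(
    "CommunityEnrichment [%s]: p = %.3g (n_boot = %d, %d within values)\n",
    object@metric, object@pValue, object@nBoot, length(object@within)))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf(
    "Level-1 sharing: chi-sq = %.2f (%d dof, p = %.3g); same within %.3f vs overall %.3f\n",
    object@chiSq, object@dof, object@p, object@fracSameWithin,
    object@fracSameOverall))
})

setMethod("show", "OverlapMatrix", function(object) {
  cat(sprintf("OverlapMatrix (%s): %d x %d\n", object@mode,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "PhenotypeDendrogram", function(object) {
  n <- length(object@clusters)
  cat("PhenotypeDendrogram over", length(object@hclust$labels), "terms,",
      n, "internal nodes\n")
  if (!all(is.na(object@au)))
    cat(sprintf("  AU >= 0.95 for %d clusters (n_boot = %d)\n",
                sum(object@au >= 0.95, na.rm = TRUE), object@nBoot))
})

setMethod("show", "SyntheticConfig", function(object) {
  p <- object@params
  cat(sprintf(
    "SyntheticConfig: %d genes in %d modules, seed %d, fidelity %.2f\n",
    p$nGenes, p$nModules, p$seed, p$moduleFidelity))
})
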