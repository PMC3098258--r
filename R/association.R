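# Pairwise association score d:
# For a pair of objects (genes; level-L terms after transposition) and a
# feature (level-L phenotype column; gene after transposition), the two
# granularity-weight vectors over the annotated descendant-or-self
# terms of the feature are compared with a two-sided two-sample
# Wilcoxon rank-sum test. A large p-value means indistinguishable
# annotation-weight profiles, i.e. similarity. Raw p-values are pooled
# across all pair x feature combinations, FDR-corrected, and d(i1, i2)
# is the mean corrected similarity over ALL features. Under the default
# "shared" gating only features annotated for BOTH objects are scored
# (others contribute 0), so d is driven by shared phenotypes and pairs
# sharing none have d = 0 exactly; the "either" gating also scores
# features annotated for just one member.

# Two-sided two-sample Wilcoxon rank-sum p-value.
# Exact null (pwilcox) when tie-free and both sides have <= `exactMax`
# observations; otherwise normal approximation with tie and continuity
# correction. All-tied degenerate data returns p = 1.
rankSumP <- function(u, v, exactMax = 10L) {
  n1 <- length(u); n2 <- length(v)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  z <- c(u, v)
  r <- rank(z)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(z) > 0L
  if (!ties && n1 <= exactMax && n2 <= exactMax) {
    p <- if (W > n1 * n2 / 2)
      2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
    else
      2 * stats::pwilcox(W, n1, n2)
    return(min(p, 1))
  }
  nt <- table(z)
  tieTerm <- sum(nt^3 - nt)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - tieTerm / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)  # every observation tied
  zc <- W - n1 * n2 / 2
  zc <- (zc - sign(zc) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE)))
}

# Internal lookup: per (object, column) weight lists, plus the
# dataset-level domain size of each column (number of distinct raw
# annotated terms at-or-below the column term).
tripleIndex <- function(B) {
  tr <- B@triples
  objs <- rownames(B@values)
  cols <- colnames(B@values)
  oi <- match(tr$object, objs)
  ci <- match(tr$column, cols)
  key <- (as.numeric(oi) - 1) * length(cols) + ci
  list(objs = objs, cols = cols,
       weights = split(tr$weight, key),
       domSize = vapply(split(tr$term, ci),
                        function(tt) length(unique(tt)), 0L),
       colByObj = lapply(split(ci, oi), unique),
       objByCol = lapply(split(oi, ci), unique))
}

#' Per-feature similarity score for one pair
#'
#' The raw (uncorrected) two-sided Wilcoxon p comparing the granularity
#' weight profiles of two rows of a biadjacency matrix under one column
#' term. Each profile is the vector over the column's annotated
#' descendant-or-self terms (annotated by any gene in the data set),
#' holding the object's granularity weights where it is annotated and 0
#' elsewhere. Returns \code{NA} (the no-signal sentinel) when neither
#' object is annotated under the column.
#'
#' @param B a \linkS4class{WeightedBiadjacency}.
#' @param i1,i2 two distinct row names.
#' @param j a column name.
#' @return p-value in [0, 1], or NA if no signal.
#' @export
pairPhenotypeScore <- function(B, i1, i2, j) {
  stopifnot(is(B, "WeightedBiadjacency"), i1 != i2)
  rn <- rownames(B@values); cn <- colnames(B@values)
  if (!all(c(i1, i2) %in% rn)) stop("unknown row id")
  if (!j %in% cn) stop("unknown column id: ", j)
  tr <- B@triples
  under <- tr$column == j
  w1 <- tr$weight[under & tr$object == i1]
  w2 <- tr$weight[under & tr$object == i2]
  if (!length(w1) && !length(w2)) return(NA_real_)
  pairProfileP(w1, w2, length(unique(tr$term[under])))
}

# Zero-pad two positive weight profiles to the column's domain size D
# (the count of annotated descendant-or-self terms), then rank-sum.
pairProfileP <- function(w1, w2, D) {
  rankSumP(c(w1, numeric(D - length(w1))),
           c(w2, numeric(D - length(w2))))
}

#' FDR correction of pooled p-values
#'
#' Benjamini-Hochberg q-values over the pooled pair x feature p-value
#' collection (the default correction of the association pipeline), or
#' no correction.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method "BH" (default) or "none".
#' @return q-values, monotone in p with q >= p for BH.
#' @export
fdrCorrect <- function(p, method = c("BH", "none")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value collection")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (method == "none") p else stats::p.adjust(p, method = "BH")
}

#' Pairwise association matrix of d scores
#'
#' Runs the full association pipeline on a weighted biadjacency matrix:
#' enumerate row pairs sharing at least one column (all other pairs
#' have d = 0 by construction), score the gated columns of each pair
#' with the Wilcoxon profile similarity, pool and FDR-correct the
#' p-values, and average corrected similarities over all columns.
#' Applying it to \code{t(B)} yields the phenotype-side matrix through
#' the identical code path.
#'
#' Gating decides which columns count as signal for a pair: under
#' "shared" (the canonical default) only columns annotated for both
#' members are scored, so d is proportional to the FDR-weighted number
#' of shared level-L phenotypes and pairs sharing none score exactly 0;
#' under "either" columns annotated for a single member are scored too
#' (their one-sided comparisons typically yield small similarity).
#'
#' @param B a \linkS4class{WeightedBiadjacency}.
#' @param correction correction passed to \code{\link{fdrCorrect}}.
#' @param gating "shared" (default) or "either"; see Details.
#' @param keepPerFeature keep the long per-pair-per-feature score table
#'   in the result (memory-heavy; default FALSE).
#' @return an \linkS4class{AssociationMatrix}.
#' @export
associationMatrix <- function(B, correction = c("BH", "none"),
                              gating = c("shared", "either"),
                              keepPerFeature = FALSE) {
  correction <- match.arg(correction)
  gating <- match.arg(gating)
  stopifnot(is(B, "WeightedBiadjacency"))
  ix <- tripleIndex(B)
  nObj <- length(ix$objs); nCol <- length(ix$cols)
  # candidate pairs: co-annotated under >= 1 column
  pairs <- unique(unlist(lapply(ix$objByCol, function(os) {
    if (length(os) < 2L) return(NULL)
    m <- utils::combn(sort(os), 2L)
    paste(m[1L, ], m[2L, ])
  }), use.names = FALSE))
  D <- matrix(0, nObj, nObj, dimnames = list(ix$objs, ix$objs))
  if (!length(pairs)) {
    return(new("AssociationMatrix", values = D, kind = B@kind,
               level = B@level, perFeature = emptyPerFeature()))
  }
  pm <- do.call(rbind, strsplit(pairs, " ", fixed = TRUE))
  pa <- as.integer(pm[, 1]); pb <- as.integer(pm[, 2])
  ctxList <- vector("list", length(pa))
  for (k in seq_along(pa)) {
    ca <- ix$colByObj[[as.character(pa[k])]]
    cb <- ix$colByObj[[as.character(pb[k])]]
    ctxList[[k]] <- if (gating == "shared") intersect(ca, cb)
                    else union(ca, cb)
  }
  nScores <- sum(lengths(ctxList))
  pRaw <- numeric(nScores)
  pairIdx <- integer(nScores)
  ctxIdx <- integer(nScores)
  weights <- ix$weights
  pos <- 0L
  for (k in seq_along(pa)) {
    a <- pa[k]; b <- pb[k]
    for (cc in ctxList[[k]]) {
      ka <- as.character((as.numeric(a) - 1) * nCol + cc)
      kb <- as.character((as.numeric(b) - 1) * nCol + cc)
      w1 <- weights[[ka]]; w2 <- weights[[kb]]
      pos <- pos + 1L
      pRaw[pos] <- pairProfileP(
        if (is.null(w1)) numeric(0) else w1,
        if (is.null(w2)) numeric(0) else w2,
        ix$domSize[[as.character(cc)]])
      pairIdx[pos] <- k
      ctxIdx[pos] <- cc
    }
  }
  if (!pos) {
    return(new("AssociationMatrix", values = D, kind = B@kind,
               level = B@level, perFeature = emptyPerFeature()))
  }
  q <- fdrCorrect(pRaw, method = correction)
  dPer <- rowsum(q, pairIdx)  # ordered by unique pairIdx (sorted)
  dVal <- as.numeric(dPer) / nCol
  kOrd <- as.integer(rownames(dPer))
  for (m in seq_along(kOrd)) {
    k <- kOrd[m]
    D[pa[k], pb[k]] <- dVal[m]
    D[pb[k], pa[k]] <- dVal[m]
  }
  pf <- if (keepPerFeature)
    data.frame(a = ix$objs[pa[pairIdx]], b = ix$objs[pb[pairIdx]],
               feature = ix$cols[ctxIdx], p = pRaw, q = q,
               stringsAsFactors = FALSE)
  else emptyPerFeature()
  new("AssociationMatrix", values = D, kind = B@kind, level = B@level,
      perFeature = pf)
}

emptyPerFeature <- function() {
  data.frame(a = character(0), b = character(0), feature = character(0),
             p = numeric(0), q = numeric(0), stringsAsFactors = FALSE)
}

#' Threshold an association matrix into a network
#'
#' Retains edges with d >= \code{dCutoff} (self-edges never included),
#' drops isolated nodes, and reports node/edge counts. The cut-offs used
#' for the published mouse networks are available from
#' \code{\link{referenceCutoffs}}.
#'
#' @param A an \linkS4class{AssociationMatrix}.
#' @param dCutoff threshold in [0, 1].
#' @return a \linkS4class{NetworkEdgeList}.
#' @export
buildNetwork <- function(A, dCutoff) {
  stopifnot(is(A, "AssociationMatrix"), dCutoff >= 0, dCutoff <= 1)
  v <- values(A)
  ids <- rownames(v)
  ut <- which(upper.tri(v) & v >= dCutoff & v > 0, arr.ind = TRUE)
  if (!nrow(ut)) {
    warning("d_cutoff = ", dCutoff, " retains no edges")
    return(new("NetworkEdgeList",
               edges = data.frame(from = character(0), to = character(0),
                                  weight = numeric(0),
                                  stringsAsFactors = FALSE),
               nodes = character(0), dCutoff = dCutoff, kind = A@kind))
  }
  from <- ids[ut[, 1]]; to <- ids[ut[, 2]]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  e <- data.frame(from = from, to = to, weight = v[ut],
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  new("NetworkEdgeList", edges = e, nodes = sort(unique(c(e$from, e$to))),
      dCutoff = dCutoff, kind = A@kind)
}

#' Published d cut-offs for the mouse gene-phenotype networks
#'
#' The edge thresholds chosen by inspection of the d-value distribution
#' for the published mouse networks, by node kind and ontology level.
#'
#' @return data.frame(kind, level, dCutoff).
#' @export
referenceCutoffs <- function() {
  data.frame(kind = c("gene", "gene", "phenotype", "phenotype"),
             level = c(5L, 8L, 5L, 8L),
             dCutoff = c(0.009, 0.011, 0.005, 0.002),
             stringsAsFactors = FALSE)
}

#' Suggest a d cut-off from the score distribution
#'
#' Automates "inspection of the d-value distribution": returns the given
#' upper quantile of the nonzero d values.
#'
#' @param A an \linkS4class{AssociationMatrix}.
#' @param quantile upper-quantile probability in (0, 1); default 0.9.
#' @return a numeric cut-off.
#' @export
suggestCutoff <- function(A, quantile = 0.9) {
  stopifnot(quantile > 0, quantile < 1)
  v <- values(A)
  nz <- v[upper.tri(v)]
  nz <- nz[nz > 0]
  if (!length(nz)) stop("association matrix has no nonzero scores")
  unname(stats::quantile(nz, quantile))
}

#' Convert a network to an igraph object
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @param weighted carry edge weights (default TRUE).
#' @return an undirected \code{igraph} graph.
#' @export
asIgraph <- function(net, weighted = TRUE) {
  e <- edges(net)
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodeIds(net)))
  if (weighted && nrow(e)) igraph::E(g)$weight <- e$weight
  g
}

#' Export a network edge list
#'
#' Writes the three-column (node, node, weight) TSV, or GraphML for
#' external viewers.
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @param path output path.
#' @param format "tsv" or "graphml".
#' @export
exportNetwork <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") writeTsv(edges(net), path)
  else igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}
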