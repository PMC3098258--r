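# Topology diagnostics are computed on the binarized graph: P(k) and
# C(k) are the classical unweighted quantities, and the power-law
# exponent is estimated by least squares on the log-log plot, matching
# the line-of-best-fit convention used for these networks.

#' Local clustering coefficients
#'
#' Classical (unweighted) local clustering coefficient per node; nodes
#' of degree < 2 get C = 0.
#'
#' @param net a \linkS4class{NetworkEdgeList} or igraph graph.
#' @return named numeric vector node -> C in [0, 1].
#' @export
clusteringCoefficients <- function(net) {
  g <- if (is(net, "NetworkEdgeList")) asIgraph(net, weighted = FALSE)
       else net
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  stats::setNames(cc, igraph::V(g)$name)
}

#' Degree distribution and clustering profile with power-law fit
#'
#' Empirical P(k) over the binarized network, mean local clustering
#' coefficient C(k) per degree, and least-squares fits on log-log axes:
#' gamma_hat is minus the slope of log P(k) on log k over nonzero,
#' positive-degree bins; ckSlope is the analogous slope for C(k) over
#' bins with C > 0. With fewer than 3 distinct positive degrees the fit
#' is flagged degenerate and the estimates are NA.
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @return a \linkS4class{DegreeProfile}.
#' @export
degreeProfile <- function(net) {
  g <- asIgraph(net, weighted = FALSE)
  deg <- igraph::degree(g)
  tab <- table(deg)
  k <- as.integer(names(tab))
  Pk <- as.numeric(tab) / length(deg)
  ccNode <- clusteringCoefficients(net)
  Ck <- vapply(k, function(kk) mean(ccNode[deg == kk]), 0)
  pos <- k > 0
  if (sum(pos) < 3L) {
    return(new("DegreeProfile", k = k, Pk = Pk, Ck = Ck,
               gammaHat = NA_real_, fitR2 = NA_real_,
               ckSlope = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(log(Pk[pos]) ~ log(k[pos]))
  gammaHat <- -unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  cpos <- pos & Ck > 0
  ckSlope <- if (sum(cpos) >= 3L)
    unname(stats::coef(stats::lm(log(Ck[cpos]) ~ log(k[cpos])))[2])
  else NA_real_
  new("DegreeProfile", k = k, Pk = Pk, Ck = Ck, gammaHat = gammaHat,
      fitR2 = r2, ckSlope = ckSlope, degenerate = FALSE)
}

#' Export a degree profile as TSV
#'
#' @param profile a \linkS4class{DegreeProfile}.
#' @param path output path.
#' @export
exportDegreeProfile <- function(profile, path) {
  writeTsv(data.frame(k = profile@k, Pk = profile@Pk, Ck = profile@Ck),
           path)
}

#' Degree-preserving rewiring null model
#'
#' Generates \code{nReps} randomly rewired versions of the network by
#' repeated double-edge swaps (self-loops and multi-edges rejected), so
#' every replicate keeps the exact degree multiset. For each replicate
#' the mean local clustering coefficient and the spectral-partition
#' modularity Q are recorded; one-sided empirical p-values give the
#' fraction of replicates at or above the observed statistics.
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @param nReps number of replicates (1000 in the published analysis).
#' @param swapsPerEdge double-edge swap attempts per edge (default 10).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param refine passed to \code{\link{newmanSpectral}} for the null Q.
#' @return a \linkS4class{RewiringNull}.
#' @export
rewireNull <- function(net, nReps = 1000L, swapsPerEdge = 10L, seed,
                       refine = TRUE) {
  stopifnot(is(net, "NetworkEdgeList"), !missing(seed))
  g <- asIgraph(net, weighted = FALSE)
  ne <- igraph::ecount(g)
  if (ne < 2L) stop("too few edges to rewire")
  obsC <- mean(clusteringCoefficients(net))
  obsQ <- modularityQ(newmanSpectral(net, refine = refine))
  nullC <- numeric(nReps)
  nullQ <- numeric(nReps)
  degObs <- sort(igraph::degree(g))
  nMatched <- 0L
  set.seed(seed)
  for (r in seq_len(nReps)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = swapsPerEdge * ne))
    if (identical(sort(igraph::degree(gr)), degObs))
      nMatched <- nMatched + 1L
    cc <- igraph::transitivity(gr, type = "local", isolates = "zero")
    cc[is.na(cc)] <- 0
    nullC[r] <- mean(cc)
    nullQ[r] <- modularityQ(newmanSpectralGraph(gr, refine = refine))
  }
  if (nMatched != nReps)
    stop("internal error: a rewired replicate changed the degree multiset")
  new("RewiringNull", nReps = as.integer(nReps), nullC = nullC,
      nullQ = nullQ, observedC = obsC, observedQ = obsQ,
      pC = mean(nullC >= obsC), pQ = mean(nullQ >= obsQ),
      nDegreeMatched = nMatched, seed = as.integer(seed))
}
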