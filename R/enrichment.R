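# Community enrichment: within-community pairwise values (coexpression,
# tissue-expression similarity, GO-similarity d, phylogenetic-profile
# correlation) or interaction counts, compared against pseudo-communities
# of the same sizes resampled from the network's gene set.

#' Pairwise Pearson correlation matrix of row profiles
#'
#' Convenience wrapper: correlation between the row vectors of a
#' genes-x-samples (or genes-x-tissues / genes-x-species) matrix.
#' Zero-variance rows yield NA correlations, which downstream pair
#' pooling skips.
#'
#' @param m numeric matrix with genes as rows.
#' @return symmetric genes-x-genes correlation matrix.
#' @export
pairwiseCorrelation <- function(m) {
  suppressWarnings(stats::cor(t(m)))
}

#' Pooled within-community pairwise values
#'
#' Concatenates, over all communities, the value of \code{pairwise} for
#' every unordered pair of community members. Nodes missing from the
#' matrix are skipped (with their count attached as the "nMissing"
#' attribute); singleton communities contribute nothing; NA pairwise
#' entries are dropped.
#'
#' @param partition a \linkS4class{Partition}.
#' @param pairwise symmetric numeric matrix with dimnames.
#' @return numeric vector of within-community pairwise values.
#' @export
withinCommunityValues <- function(partition, pairwise) {
  labels <- communityLabels(partition)
  present <- names(labels)[names(labels) %in% rownames(pairwise)]
  nMissing <- length(labels) - length(present)
  vals <- numeric(0)
  for (cmt in unique(labels[present])) {
    members <- present[labels[present] == cmt]
    if (length(members) < 2L) next
    sub <- pairwise[members, members]
    vals <- c(vals, sub[upper.tri(sub)])
  }
  vals <- vals[!is.na(vals)]
  attr(vals, "nMissing") <- nMissing
  vals
}

#' Control values from resampled pseudo-communities
#'
#' For each bootstrap replicate, pseudo-communities of the same sizes as
#' the observed ones are drawn (without replacement within a replicate)
#' from the gene universe, and their within-pair values pooled across
#' replicates.
#'
#' @param sizes integer community sizes.
#' @param universe candidate node names (must contain at least
#'   \code{max(sizes)} nodes present in \code{pairwise}).
#' @param pairwise symmetric numeric matrix.
#' @param nBoot replicates (published default 1000).
#' @param seed RNG seed.
#' @return numeric vector of pooled control values.
#' @export
resampledControl <- function(sizes, universe, pairwise, nBoot = 1000L,
                             seed) {
  stopifnot(!missing(seed))
  universe <- universe[universe %in% rownames(pairwise)]
  if (max(sizes) > length(universe))
    stop("universe smaller than the largest community")
  set.seed(seed)
  out <- vector("list", nBoot)
  for (r in seq_len(nBoot)) {
    vals <- numeric(0)
    for (sz in sizes) {
      if (sz < 2L) next
      members <- sample(universe, sz)
      sub <- pairwise[members, members]
      vals <- c(vals, sub[upper.tri(sub)])
    }
    out[[r]] <- vals
  }
  vals <- unlist(out, use.names = FALSE)
  vals[!is.na(vals)]
}

#' One-sided comparison of within vs control distributions
#'
#' Two-sample Wilcoxon test of the alternative that within-community
#' values are stochastically greater than control values.
#'
#' @param within,control non-empty numeric vectors.
#' @return one-sided p-value.
#' @export
compareDistributions <- function(within, control) {
  if (!length(within) || !length(control))
    stop("both vectors must be non-empty")
  suppressWarnings(
    stats::wilcox.test(within, control,
                       alternative = "greater")$p.value)
}

#' Community enrichment for a pairwise similarity metric
#'
#' Pools within-community pairwise values, builds the resampled control,
#' and compares the two one-sidedly.
#'
#' @param partition a \linkS4class{Partition} over network nodes.
#' @param pairwise symmetric similarity matrix (see
#'   \code{\link{pairwiseCorrelation}}).
#' @param metric label recorded on the result.
#' @param nBoot resampling replicates.
#' @param seed RNG seed.
#' @param universe resampling universe; defaults to the partition nodes.
#' @return a \linkS4class{CommunityEnrichmentResult}.
#' @export
communityEnrichment <- function(partition, pairwise,
                                metric = c("expr_corr", "tissue_corr",
                                           "go_d", "phylo_corr"),
                                nBoot = 1000L, seed,
                                universe = nodeIds(partition)) {
  metric <- match.arg(metric)
  stopifnot(!missing(seed))
  within <- withinCommunityValues(partition, pairwise)
  labels <- communityLabels(partition)
  present <- names(labels)[names(labels) %in% rownames(pairwise)]
  sizes <- as.integer(table(labels[present]))
  sizes <- sizes[sizes >= 2L]
  control <- resampledControl(sizes, universe, pairwise, nBoot, seed)
  p <- compareDistributions(within, control)
  new("CommunityEnrichmentResult", metric = metric,
      within = as.numeric(within), control = control, pValue = p,
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Physical-interaction evidence types retained by default
#'
#' The experimental-system labels accepted as physical protein-protein
#' interaction evidence when parsing interaction reports.
#'
#' @return character vector of evidence labels.
#' @export
physicalEvidenceTypes <- function() {
  c("Affinity Capture-MS", "Affinity Capture-RNA",
    "Affinity Capture-Western", "Co-fractionation", "Co-localization",
    "Co-purification", "FRET", "Two-Hybrid", "Biochemical Activity",
    "Co-crystal Structure", "Far Western", "Protein-peptide",
    "Protein-RNA", "Reconstituted Complex")
}

#' Read a protein-protein interaction pair list
#'
#' TSV with two interactor columns and an optional evidence-type column;
#' rows whose evidence is not in \code{keep} are dropped; pairs are
#' canonicalized to undirected, deduplicated, self-interactions removed.
#'
#' @param path TSV path.
#' @param aCol,bCol interactor column indices.
#' @param evidenceCol evidence column index, or NA to keep everything.
#' @param keep evidence labels accepted (default
#'   \code{\link{physicalEvidenceTypes}}).
#' @param header whether the file has a header.
#' @return data.frame(a, b) of undirected interaction pairs.
#' @export
readPPI <- function(path, aCol = 1L, bCol = 2L, evidenceCol = 3L,
                    keep = physicalEvidenceTypes(), header = FALSE) {
  df <- readTsv(path, header = header)
  a <- as.character(df[[aCol]]); b <- as.character(df[[bCol]])
  if (!is.na(evidenceCol) && evidenceCol <= ncol(df)) {
    ok <- as.character(df[[evidenceCol]]) %in% keep
    a <- a[ok]; b <- b[ok]
  }
  ord <- a > b
  tmp <- a[ord]; a[ord] <- b[ord]; b[ord] <- tmp
  keepRow <- a != b & !duplicated(paste(a, b))
  data.frame(a = a[keepRow], b = b[keepRow], stringsAsFactors = FALSE)
}

#' Protein-protein interaction enrichment of communities
#'
#' Observed statistic: total number of interaction pairs whose two
#' members share a community. Null: interaction counts in same-size
#' pseudo-communities resampled from the universe. Significance is the
#' one-sided tail of the observed count in the resampled null: the
#' default "ztail" evaluates the normal-theory upper tail of the null
#' count distribution at the observed value (continuous and calibrated
#' under exchangeability); "signed-rank" is the classical one-sample
#' Wilcoxon of the null counts against the observed value, and
#' "empirical" the plain resampling rank p (lower-bounded by
#' 1 / (nBoot + 1)). See the methods vignette for why the tail form is
#' the default.
#'
#' @param partition a \linkS4class{Partition}.
#' @param ppi data.frame(a, b) from \code{\link{readPPI}}.
#' @param nBoot resampling replicates.
#' @param seed RNG seed.
#' @param universe resampling universe; defaults to partition nodes.
#' @param test "ztail" (default), "signed-rank" or "empirical".
#' @return a \linkS4class{CommunityEnrichmentResult} with metric
#'   "ppi_count": \code{within} holds the single observed count,
#'   \code{control} the null counts.
#' @export
ppiCountEnrichment <- function(partition, ppi, nBoot = 1000L, seed,
                               universe = nodeIds(partition),
                               test = c("ztail", "signed-rank",
                                        "empirical")) {
  test <- match.arg(test)
  stopifnot(!missing(seed))
  labels <- communityLabels(partition)
  ppi <- ppi[ppi$a %in% universe & ppi$b %in% universe, , drop = FALSE]
  if (!nrow(ppi)) {
    warning("no interaction overlaps the network genes; p undefined")
    return(new("CommunityEnrichmentResult", metric = "ppi_count",
               within = 0, control = numeric(0), pValue = NA_real_,
               nBoot = as.integer(nBoot), seed = as.integer(seed)))
  }
  # interactions with both ends inside a community, summed over the
  # (pseudo-)communities; pseudo-communities are drawn independently,
  # so the null statistic is exchangeable with the observed one
  countWithin <- function(memberSets) {
    sum(vapply(memberSets, function(members)
      sum(ppi$a %in% members & ppi$b %in% members), 0))
  }
  observed <- countWithin(split(names(labels), labels))
  sizes <- as.integer(table(labels))
  set.seed(seed)
  nullCounts <- numeric(nBoot)
  for (r in seq_len(nBoot)) {
    nullCounts[r] <- countWithin(lapply(sizes, function(sz)
      sample(universe, sz)))
  }
  s <- stats::sd(nullCounts)
  p <- switch(test,
    ztail = if (s == 0) as.numeric(observed <= nullCounts[1])
            else stats::pnorm(observed, mean = mean(nullCounts),
                              sd = s * sqrt(1 + 1 / nBoot),
                              lower.tail = FALSE),
    `signed-rank` = if (s == 0 && nullCounts[1] == observed) 1
                    else suppressWarnings(
                      stats::wilcox.test(nullCounts, mu = observed,
                                         alternative = "less")$p.value),
    empirical = (1 + sum(nullCounts >= observed)) / (nBoot + 1))
  new("CommunityEnrichmentResult", metric = "ppi_count",
      within = observed, control = nullCounts, pValue = p,
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Gene Ontology similarity enrichment of communities
#'
#' Runs the full association pipeline (biadjacency at the branch's
#' analysis level, Wilcoxon profile similarity, FDR correction, mean d)
#' on each GO branch's annotations, then compares within-community d
#' values against resampled controls. The default levels (biological
#' process 5, cellular component 5, molecular function 2) follow the
#' most frequent annotation level of each branch.
#'
#' @param partition a \linkS4class{Partition}.
#' @param goAnnotations named list of \linkS4class{AnnotationSet}s, one
#'   per branch.
#' @param goDags named list of annotated \linkS4class{OntologyDAG}s (or
#'   un-annotated: granularity is computed here), same names.
#' @param levels named integer analysis level per branch.
#' @param nBoot,seed as in \code{\link{communityEnrichment}}.
#' @return named list of \linkS4class{CommunityEnrichmentResult}, one
#'   per branch (branches with no usable annotation are skipped).
#' @export
goSimilarityD <- function(partition, goAnnotations, goDags,
                          levels = c(BP = 5L, CC = 5L, MF = 2L),
                          nBoot = 1000L, seed) {
  stopifnot(!missing(seed))
  out <- list()
  for (br in names(goAnnotations)) {
    ann <- goAnnotations[[br]]
    dag <- goDags[[br]]
    if (is.null(dag) || !nrow(records(ann))) next
    if (!length(dag@granularity))
      dag <- annotateGranularity(dag, ann)
    L <- levels[[br]]
    Bgo <- tryCatch(buildBiadjacency(ann, dag, L), error = function(e) NULL)
    if (is.null(Bgo)) next
    Ago <- associationMatrix(Bgo)
    out[[br]] <- communityEnrichment(
      partition, values(Ago), metric = "go_d", nBoot = nBoot,
      seed = deriveSeed(seed, paste0("go_", br)))
  }
  out
}

#' GO over-representation in network hubs
#'
#' One-tailed Fisher's exact test per GO term on the 2x2 table of hub
#' membership against term annotation over the gene universe, with BH
#' q-values. Terms annotating no universe gene are skipped.
#'
#' @param hubs character vector of hub genes.
#' @param universe background gene set (must contain the hubs).
#' @param goAnnotations an \linkS4class{AnnotationSet} of gene-GO links
#'   (one branch, or all branches pooled).
#' @param minGenes skip terms annotating fewer universe genes (default 2).
#' @return data.frame(term, nHub, nUniverse, oddsRatio, p, q) sorted by p.
#' @export
hubGOFisher <- function(hubs, universe, goAnnotations, minGenes = 2L) {
  stopifnot(all(hubs %in% universe))
  df <- records(goAnnotations)
  df <- df[df$gene %in% universe, , drop = FALSE]
  if (!nrow(df)) stop("no GO annotation overlaps the universe")
  terms <- unique(df$term)
  byTerm <- split(df$gene, df$term)
  nU <- length(universe); nH <- length(hubs)
  res <- lapply(terms, function(tm) {
    genes <- unique(byTerm[[tm]])
    if (length(genes) < minGenes) return(NULL)
    inHub <- sum(genes %in% hubs)
    tab <- matrix(c(inHub, length(genes) - inHub,
                    nH - inHub, nU - nH - (length(genes) - inHub)),
                  2, 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(term = tm, nHub = inHub, nUniverse = length(genes),
               oddsRatio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no GO term passed the minimum-gene filter")
  res$q <- fdrCorrect(res$p)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chi-square test of level-1 term sharing within communities
#'
#' For every unordered gene pair the number of level-1 phenotype terms
#' annotated to both (columns of the level-1 biadjacency where both rows
#' are positive) is binned as 0, 1, 2 or >= 3. The 2 x 4 contingency
#' table of within-community pairs against all pairs gives a chi-square
#' with 3 degrees of freedom; the fractions of pairs sharing at least
#' one term within communities and overall are reported alongside.
#'
#' @param partition a \linkS4class{Partition}.
#' @param B1 the level-1 \linkS4class{WeightedBiadjacency} (gene rows).
#' @return a \linkS4class{ContingencyResult}.
#' @export
level1SharingChisq <- function(partition, B1) {
  labels <- communityLabels(partition)
  if (!length(labels)) stop("no communities")
  M <- values(B1) > 0
  genes <- intersect(names(labels), rownames(M))
  if (length(genes) < 2L) stop("fewer than two partition genes in B1")
  M <- M[genes, , drop = FALSE]
  shared <- tcrossprod(M * 1)  # pairwise shared level-1 term counts
  ut <- upper.tri(shared)
  sameCom <- outer(labels[genes], labels[genes], "==")
  binify <- function(x) {
    f <- cut(x, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", ">=3"))
    table(f)
  }
  withinCounts <- binify(shared[ut & sameCom])
  allCounts <- binify(shared[ut])
  tab <- rbind(within = as.integer(withinCounts),
               all = as.integer(allCounts))
  colnames(tab) <- names(withinCounts)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chiSq <- unname(cs$statistic)
  if (is.nan(chiSq)) chiSq <- 0  # identical margins (degenerate)
  fracW <- mean(shared[ut & sameCom] >= 1)
  fracA <- mean(shared[ut] >= 1)
  new("ContingencyResult", table = tab, chiSq = chiSq,
      dof = as.integer(cs$parameter),
      p = if (is.nan(chiSq) || chiSq == 0) 1 else unname(cs$p.value),
      fracSameWithin = fracW, fracSameOverall = fracA)
}
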