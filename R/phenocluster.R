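# Hierarchical clustering of high-level phenotype terms by gene
# sharing: columns of the level-1 biadjacency matrix are clustered with
# distance 1 - Pearson correlation and average linkage, and cluster
# uncertainty is assessed by multiscale bootstrap resampling of the
# gene rows, giving plain bootstrap proportions (BP) and approximately
# unbiased (AU) support values.

# 1 - cor distance between matrix columns; zero-variance columns give
# undefined correlations, treated as distance 1.
corDistance <- function(m, warnConstant = TRUE) {
  cm <- suppressWarnings(stats::cor(m))
  if (anyNA(cm)) {
    if (warnConstant)
      warning("constant column(s): undefined correlations set to distance 1")
    cm[is.na(cm)] <- 0
  }
  stats::as.dist(1 - cm)
}

# Leaf-label sets of every internal node of an hclust tree, as sorted
# character vectors (element i = merge step i).
hclustClusters <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[i, j]
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[i]] <- members
  }
  lapply(sets, function(ix) sort(hc$labels[ix]))
}

clusterKey <- function(labels) paste(labels, collapse = "\r")

#' Cluster level-1 phenotype terms by gene sharing
#'
#' Average-linkage agglomerative clustering of the columns of a
#' biadjacency matrix, with distance 1 - Pearson correlation between
#' the raw weighted columns. Support values are NA until
#' \code{\link{bootstrapSupport}} is run.
#'
#' @param B1 a \linkS4class{WeightedBiadjacency} with >= 3 columns
#'   (typically the level-1 matrix).
#' @return a \linkS4class{PhenotypeDendrogram}.
#' @export
clusterPhenotypes <- function(B1) {
  m <- values(B1)
  if (ncol(m) < 3L) stop("need at least 3 term columns to cluster")
  hc <- stats::hclust(corDistance(m), method = "average")
  cl <- hclustClusters(hc)
  nInt <- length(cl)
  new("PhenotypeDendrogram", hclust = hc, clusters = cl,
      bp = rep(NA_real_, nInt), au = rep(NA_real_, nInt),
      nBoot = 0L, scales = numeric(0), seed = NA_integer_)
}

#' Multiscale bootstrap support for phenotype clusters
#'
#' Resamples the gene rows of the biadjacency matrix with replacement
#' at several scales r (replicate size = round(r * n_rows)), recomputes
#' the average-linkage tree for each replicate, and records how often
#' each observed cluster reappears. BP is the recovery frequency at
#' scale 1; AU extrapolates across scales by weighted least squares on
#' qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r), giving
#' AU = 1 - pnorm(v - c). Clusters recovered identically at every scale
#' (no cross-scale variation) take AU = BP; the root cluster has
#' support 1 by definition. Scales yielding fewer than 3 rows are
#' skipped.
#'
#' @param B1 a \linkS4class{WeightedBiadjacency} with >= 3 columns.
#' @param nBoot total bootstrap replicates, split evenly across scales
#'   (published default 1e4; must be >= 100).
#' @param scales row-resampling scale factors (default 0.5 ... 1.4).
#' @param seed RNG seed.
#' @return a \linkS4class{PhenotypeDendrogram} with bp and au filled.
#' @export
bootstrapSupport <- function(B1, nBoot = 10000L,
                             scales = seq(0.5, 1.4, by = 0.1), seed) {
  stopifnot(!missing(seed), nBoot >= 100L)
  m <- values(B1)
  dend <- clusterPhenotypes(B1)
  keys <- vapply(dend@clusters, clusterKey, "")
  n <- nrow(m)
  useScale <- round(scales * n) >= 3L
  if (!any(useScale)) stop("every scale yields fewer than 3 rows")
  scales <- scales[useScale]
  perScale <- max(1L, floor(nBoot / length(scales)))
  counts <- matrix(0L, length(keys), length(scales))
  set.seed(seed)
  for (si in seq_along(scales)) {
    msize <- round(scales[si] * n)
    for (r in seq_len(perScale)) {
      rows <- sample.int(n, msize, replace = TRUE)
      hc <- stats::hclust(corDistance(m[rows, , drop = FALSE],
                                      warnConstant = FALSE),
                          method = "average")
      repKeys <- vapply(hclustClusters(hc), clusterKey, "")
      counts[, si] <- counts[, si] + as.integer(keys %in% repKeys)
    }
  }
  bpAll <- counts / perScale
  # BP reported at the scale closest to 1
  s1 <- which.min(abs(scales - 1))
  bp <- bpAll[, s1]
  au <- vapply(seq_along(keys), function(i)
    auFromMultiscale(bpAll[i, ], scales, perScale), 0)
  # root cluster contains every leaf in every replicate
  root <- which.max(lengths(dend@clusters))
  bp[root] <- 1; au[root] <- 1
  dend@bp <- bp
  dend@au <- au
  dend@nBoot <- as.integer(perScale * length(scales))
  dend@scales <- scales
  dend@seed <- as.integer(seed)
  dend
}

# Weighted least squares fit of the multiscale z-values; returns AU.
auFromMultiscale <- function(bpScales, scales, perScale) {
  if (max(bpScales) == min(bpScales)) return(bpScales[1])  # no variation
  eps <- 1 / (perScale + 1)
  bpc <- pmin(pmax(bpScales, eps), 1 - eps)
  z <- stats::qnorm(1 - bpc)
  w <- perScale * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  min(1, max(0, 1 - stats::pnorm(v - cc)))
}

#' Export a phenotype dendrogram
#'
#' Writes the tree as Newick with AU support as internal node labels,
#' or the merge table (step, child1, child2, height, bp, au) as TSV.
#'
#' @param dend a \linkS4class{PhenotypeDendrogram}.
#' @param path output path.
#' @param format "newick" or "tsv".
#' @export
exportDendrogram <- function(dend, path, format = c("newick", "tsv")) {
  format <- match.arg(format)
  hc <- dend@hclust
  if (format == "tsv") {
    df <- data.frame(step = seq_len(nrow(hc$merge)),
                     child1 = hc$merge[, 1], child2 = hc$merge[, 2],
                     height = hc$height, bp = dend@bp, au = dend@au)
    writeTsv(df, path)
    return(invisible(path))
  }
  node <- function(i) {
    kids <- vapply(1:2, function(j) {
      v <- hc$merge[i, j]
      if (v < 0) hc$labels[-v] else node(v)
    }, "")
    sup <- if (is.na(dend@au[i])) "" else
      format(dend@au[i], digits = 4, scientific = FALSE)
    sprintf("(%s,%s)%s:%s", kids[1], kids[2], sup,
            format(hc$height[i], digits = 6, scientific = FALSE))
  }
  writeLines(paste0(sub(":[^:]*$", "", node(nrow(hc$merge))), ";"), path)
  invisible(path)
}
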