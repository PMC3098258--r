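# Mapping gene communities to high-level phenotype groups, and
# comparing community sets across networks. The overlap model: two
# independent uniform random subsets of sizes x and y from an N-element
# universe intersect in Z elements; Z is hypergeometric, and the
# reported p is the upper tail P(Z >= z_obs).

#' Highest-scoring level-1 term per gene
#'
#' For each row of the level-1 biadjacency matrix, the column term with
#' the largest weight. A row whose maximum is attained by several
#' columns yields the tie sentinel \code{"<tie>"}; an all-zero row
#' yields \code{NA} (unassigned).
#'
#' @param B1 the level-1 \linkS4class{WeightedBiadjacency} (gene rows).
#' @param gene optional single gene id; default returns all genes.
#' @return named character vector gene -> term id, \code{"<tie>"} or NA.
#' @export
highestScoringLevel1 <- function(B1, gene = NULL) {
  v <- values(B1)
  if (!is.null(gene)) {
    if (!gene %in% rownames(v)) stop("unknown gene: ", gene)
    v <- v[gene, , drop = FALSE]
  }
  out <- apply(v, 1L, function(row) {
    mx <- max(row)
    if (mx <= 0) return(NA_character_)
    top <- colnames(v)[row == mx]
    if (length(top) > 1L) "<tie>" else top
  })
  out
}

#' Probability of an intersection of exactly z elements
#'
#' P(|X ∩ Y| = z) for independent uniform subsets X, Y of sizes x and y
#' drawn from an N-element universe: choose(x, z) * choose(N - x, y - z)
#' / choose(N, y). Infeasible z (z > min(x, y) or y - z > N - x) has
#' probability 0.
#'
#' @param N universe size.
#' @param x,y subset sizes (each <= N).
#' @param z intersection size(s), 0 <= z.
#' @return probability (vectorized over z).
#' @export
intersectionPmf <- function(N, x, y, z) {
  stopifnot(N >= 0, x >= 0, y >= 0, x <= N, y <= N, all(z >= 0))
  stats::dhyper(z, m = x, n = N - x, k = y)
}

#' Upper-tail probability of the intersection size
#'
#' P(Z >= z_obs) under \code{\link{intersectionPmf}}; \code{zObs = 0}
#' gives exactly 1.
#'
#' @inheritParams intersectionPmf
#' @param zObs observed intersection size.
#' @return upper-tail p-value.
#' @export
intersectionTailP <- function(N, x, y, zObs) {
  stopifnot(zObs >= 0)
  stats::phyper(zObs - 1, m = x, n = N - x, k = y, lower.tail = FALSE)
}

#' Mean overlap fraction of two sets
#'
#' (|A ∩ B| / |A| + |A ∩ B| / |B|) / 2 — the average of the fraction of
#' common elements for each set. Symmetric; 1 for identical sets, 0 for
#' disjoint ones.
#'
#' @param setA,setB non-empty character vectors.
#' @return overlap fraction in [0, 1].
#' @export
overlapFraction <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  if (!length(setA) || !length(setB)) stop("sets must be non-empty")
  z <- length(intersect(setA, setB))
  (z / length(setA) + z / length(setB)) / 2
}

#' Community-to-community overlap matrix across two partitions
#'
#' All-against-all comparison of the communities of two partitions,
#' optionally translating the second partition's node ids into the
#' first's namespace through a two-column orthology table. Nodes that
#' do not map into the common universe are excluded from community
#' sizes and from N. Values are either -log10 of the intersection
#' upper-tail probability or the mean overlap fraction.
#'
#' @param partitionA,partitionB \linkS4class{Partition} objects.
#' @param idMap optional data.frame (or 2-column TSV path) mapping
#'   partitionB ids (column 1) to partitionA's namespace (column 2).
#' @param mode "tail_p" (default) or "fraction".
#' @return an \linkS4class{OverlapMatrix} (rows = partitionA
#'   communities, columns = partitionB communities).
#' @export
crossPartitionMatrix <- function(partitionA, partitionB, idMap = NULL,
                                 mode = c("tail_p", "fraction")) {
  mode <- match.arg(mode)
  labA <- communityLabels(partitionA)
  labB <- communityLabels(partitionB)
  if (!is.null(idMap)) {
    if (is.character(idMap) && length(idMap) == 1L)
      idMap <- readTsv(idMap, header = FALSE)
    lut <- stats::setNames(as.character(idMap[[2]]),
                           as.character(idMap[[1]]))
    mapped <- lut[names(labB)]
    keep <- !is.na(mapped) & !duplicated(mapped)
    labB <- stats::setNames(labB[keep], mapped[keep])
  }
  universe <- intersect(names(labA), names(labB))
  if (!length(universe))
    stop("partitions share no nodes after id mapping")
  labA <- labA[universe]; labB <- labB[universe]
  commA <- sort(unique(labA)); commB <- sort(unique(labB))
  N <- length(universe)
  vals <- matrix(0, length(commA), length(commB),
                 dimnames = list(paste0("A", commA), paste0("B", commB)))
  for (i in seq_along(commA)) {
    sa <- names(labA)[labA == commA[i]]
    for (j in seq_along(commB)) {
      sb <- names(labB)[labB == commB[j]]
      z <- length(intersect(sa, sb))
      vals[i, j] <- if (mode == "fraction")
        (z / length(sa) + z / length(sb)) / 2
      else
        -log10(max(intersectionTailP(N, length(sa), length(sb), z),
                   .Machine$double.xmin))
    }
  }
  new("OverlapMatrix", values = vals, mode = mode, N = as.integer(N))
}

#' Community-to-group overlap matrix within one network
#'
#' Maps communities of a partition to the groups defined by the
#' highest-scoring level-1 term of each gene (ties and unassigned genes
#' form no group). Cells hold -log10 of the intersection upper-tail
#' probability with N = the number of partitioned genes carrying a
#' group. Rows are ordered by hierarchical clustering (Euclidean
#' distance, complete linkage) for heat-map display.
#'
#' @param partition a \linkS4class{Partition}.
#' @param B1 level-1 \linkS4class{WeightedBiadjacency}.
#' @param cluster reorder rows by hierarchical clustering (default TRUE).
#' @return an \linkS4class{OverlapMatrix} with mode "tail_p".
#' @export
communityGroupMatrix <- function(partition, B1, cluster = TRUE) {
  labels <- communityLabels(partition)
  assign <- highestScoringLevel1(B1)
  assign <- assign[!is.na(assign) & assign != "<tie>"]
  genes <- intersect(names(labels), names(assign))
  if (!length(genes)) stop("no partitioned gene carries a level-1 group")
  labels <- labels[genes]; assign <- assign[genes]
  comms <- sort(unique(labels)); groups <- sort(unique(assign))
  N <- length(genes)
  vals <- matrix(0, length(comms), length(groups),
                 dimnames = list(paste0("C", comms), groups))
  for (i in seq_along(comms)) {
    sa <- genes[labels == comms[i]]
    for (j in seq_along(groups)) {
      sb <- genes[assign == groups[j]]
      z <- length(intersect(sa, sb))
      vals[i, j] <- -log10(max(
        intersectionTailP(N, length(sa), length(sb), z),
        .Machine$double.xmin))
    }
  }
  if (cluster && nrow(vals) > 2L) {
    ord <- stats::hclust(stats::dist(vals))$order
    vals <- vals[ord, , drop = FALSE]
  }
  new("OverlapMatrix", values = vals, mode = "tail_p", N = as.integer(N))
}

#' Write an overlap matrix as TSV
#'
#' @param om an \linkS4class{OverlapMatrix}.
#' @param path output path.
#' @export
writeOverlapMatrix <- function(om, path) {
  writeMatrixTsv(values(om), path)
}
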