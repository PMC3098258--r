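# Newman's spectral community extraction: recursive bisection by the
# leading eigenvector of the (generalized) modularity matrix, with an
# optional Kernighan-Lin style fine-tuning sweep after each split, on
# the binarized graph. Deterministic: vertices are processed in sorted
# name order, zero eigenvector entries join the + group, and the sign
# ambiguity of the eigenvector is resolved by placing the first (lexico-
# graphically smallest) vertex of the subgroup in the + group.

#' Extract communities with Newman's spectral method
#'
#' Recursively bisects the network by the leading eigenvector of the
#' modularity matrix B = A - k k'/2m (generalized form for subgroups),
#' accepting a split only when it increases modularity Q, optionally
#' fine-tuning each split by greedy single-vertex moves. Connected
#' components separate naturally since splitting between components
#' always increases Q.
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @param refine run Kernighan-Lin style refinement after each split
#'   (default TRUE).
#' @return a \linkS4class{Partition} with community labels and Q.
#' @export
newmanSpectral <- function(net, refine = TRUE) {
  stopifnot(is(net, "NetworkEdgeList"))
  if (!length(nodeIds(net))) stop("empty network")
  newmanSpectralGraph(asIgraph(net, weighted = FALSE), refine = refine)
}

# Same, from an igraph object (used by the rewiring null).
newmanSpectralGraph <- function(g, refine = TRUE, tol = 1e-10) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  n <- length(nodes)
  if (n == 0L) stop("empty network")
  ord <- order(nodes)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A[ord, ord, drop = FALSE] > 0) + 0
  diag(A) <- 0
  nodes <- nodes[ord]
  k <- rowSums(A)
  m2 <- sum(k)  # = 2m
  labels <- rep(1L, n)
  names(labels) <- nodes
  if (m2 == 0) {  # edgeless: everything in one community, Q = 0
    return(new("Partition", labels = labels, Q = 0,
               method = "newman-spectral", refined = refine))
  }
  Bmod <- A - outer(k, k) / m2
  nextLab <- 0L
  recurse <- function(idx) {
    nextLab <<- nextLab + 1L
    labels[idx] <<- nextLab
    ng <- length(idx)
    if (ng < 2L) return(invisible(NULL))
    Bg <- Bmod[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    eig <- eigen(Bg, symmetric = TRUE)
    if (eig$values[1] <= tol) return(invisible(NULL))  # indivisible
    v1 <- eig$vectors[, 1]
    s <- ifelse(v1 >= 0, 1, -1)  # zeros assigned to +
    if (s[1] < 0) s <- -s        # sign tie-break
    if (refine) s <- klRefine(Bg, s, tol)
    dQ <- drop(crossprod(s, Bg %*% s)) / (2 * m2)
    if (dQ <= tol || all(s == 1) || all(s == -1))
      return(invisible(NULL))
    recurse(idx[s > 0])
    recurse(idx[s < 0])
    invisible(NULL)
  }
  recurse(seq_len(n))
  # renumber to consecutive 1..K in order of first appearance
  labels <- stats::setNames(match(labels, unique(labels)), nodes)
  Q <- modularityFromMatrix(A, labels)
  new("Partition", labels = labels, Q = Q, method = "newman-spectral",
      refined = refine)
}

# Kernighan-Lin style refinement of a bisection vector s on the
# generalized modularity matrix Bg: repeated passes, each moving every
# vertex exactly once (greedy on the modularity gain), keeping the best
# intermediate configuration; stops when a pass fails to improve.
klRefine <- function(Bg, s, tol = 1e-10) {
  n <- length(s)
  repeat {
    Qcur <- drop(crossprod(s, Bg %*% s))
    sPass <- s
    Bs <- drop(Bg %*% sPass)
    moved <- rep(FALSE, n)
    Qtrace <- numeric(n)
    states <- matrix(0, n, n)
    Qrun <- Qcur
    for (step in seq_len(n)) {
      # gain from flipping vertex i: -4 s_i (Bg s)_i + 4 B_ii
      gains <- -4 * sPass * Bs + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      Qrun <- Qrun + gains[i]
      Bs <- Bs - 2 * sPass[i] * Bg[, i]
      sPass[i] <- -sPass[i]
      moved[i] <- TRUE
      Qtrace[step] <- Qrun
      states[step, ] <- sPass
    }
    # best non-trivial intermediate state
    okSplit <- apply(states, 1L, function(x) any(x > 0) && any(x < 0))
    cand <- which(okSplit & Qtrace > Qcur + tol)
    if (!length(cand)) return(s)
    best <- cand[which.max(Qtrace[cand])]
    s <- states[best, ]
  }
}

# Q = sum_c (e_cc - a_c^2) from a binarized adjacency matrix.
modularityFromMatrix <- function(A, labels) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  comms <- unique(labels)
  Q <- 0
  for (cmt in comms) {
    inC <- labels == cmt
    ecc <- sum(A[inC, inC]) / m2
    ac <- sum(A[inC, ]) / m2
    Q <- Q + ecc - ac^2
  }
  Q
}

#' Newman modularity of a labelled network
#'
#' Q = sum over communities of (e_cc - a_c^2) on the binarized graph,
#' where e_cc is the fraction of edges inside community c and a_c the
#' fraction of edge ends attached to it.
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @param partition a \linkS4class{Partition} (or named integer vector)
#'   covering every network node.
#' @return modularity Q.
#' @export
networkModularity <- function(net, partition) {
  labels <- if (is(partition, "Partition")) communityLabels(partition)
            else partition
  miss <- setdiff(nodeIds(net), names(labels))
  if (length(miss))
    stop("unlabeled node(s): ", paste(utils::head(miss, 5), collapse = ", "))
  g <- asIgraph(net, weighted = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A > 0) + 0
  diag(A) <- 0
  modularityFromMatrix(A, labels[rownames(A)])
}

#' Hub nodes of a network
#'
#' Nodes whose degree lies strictly above the given percentile of the
#' degree distribution; the default 80 keeps the top-20% most connected
#' nodes. In a regular graph no node exceeds the threshold, so the hub
#' set is empty.
#'
#' @param net a \linkS4class{NetworkEdgeList}.
#' @param percentile percentile threshold in (0, 100); default 80.
#' @return character vector of hub node names.
#' @export
hubNodes <- function(net, percentile = 80) {
  stopifnot(percentile > 0, percentile < 100)
  g <- asIgraph(net, weighted = FALSE)
  deg <- igraph::degree(g)
  thr <- stats::quantile(deg, percentile / 100, names = FALSE)
  sort(names(deg)[deg > thr])
}

#' Write a partition as a two-column TSV
#'
#' @param partition a \linkS4class{Partition}.
#' @param path output path.
#' @export
writePartition <- function(partition, path) {
  lab <- communityLabels(partition)
  writeTsv(data.frame(node = names(lab), community = unname(lab)), path)
}

#' Read a community membership file
#'
#' Two-column TSV (node, community); community ids are renumbered to
#' consecutive integers.
#'
#' @param path TSV path.
#' @param header whether the file has a header (default TRUE).
#' @return a \linkS4class{Partition} with Q = NA.
#' @export
readPartition <- function(path, header = TRUE) {
  df <- readTsv(path, header = header)
  lab <- stats::setNames(match(df[[2]], unique(df[[2]])),
                         as.character(df[[1]]))
  new("Partition", labels = lab, Q = NA_real_, method = "file",
      refined = FALSE)
}
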