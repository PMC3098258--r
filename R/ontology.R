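#' Parse an OBO 1.2 ontology file into an OntologyDAG
#'
#' Reads \code{[Term]} stanzas, keeping \code{id}, \code{name} and
#' \code{is_a} keys. Obsolete terms (\code{is_obsolete: true}) are dropped,
#' as are \code{is_a} links pointing at them. Only \code{is_a}
#' relationships define the DAG; \code{relationship:} lines and other
#' stanza types are ignored. The single parentless term becomes the root.
#'
#' @param path path to an OBO 1.2 flat file.
#' @return an \linkS4class{OntologyDAG} with levels unset (call
#'   \code{\link{computeLevels}} next).
#' @examples
#' obo <- c("format-version: 1.2", "", "[Term]", "id: T:0", "name: root",
#'          "", "[Term]", "id: T:1", "name: a", "is_a: T:0 ! root")
#' f <- tempfile(fileext = ".obo"); writeLines(obo, f)
#' dag <- parseOBO(f)
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- character(0); nms <- character(0); parents <- list()
  obsolete <- character(0)
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[seq(starts[s] + 1L, ends[s])]
    block <- block[nzchar(block)]
    keyed <- regmatches(block, regexec("^([A-Za-z_]+):\\s*(.*)$", block))
    bad <- which(lengths(keyed) != 3L & nzchar(block))
    if (length(bad))
      stop("malformed stanza line ", starts[s] + bad[1],
           ": '", block[bad[1]], "'")
    keys <- vapply(keyed, `[`, "", 2L)
    vals <- vapply(keyed, `[`, "", 3L)
    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id))
      stop("malformed stanza at line ", starts[s], ": missing id")
    if (any(keys == "is_obsolete" & grepl("^true", vals))) {
      obsolete <- c(obsolete, id)
      next
    }
    nm <- vals[keys == "name"][1]
    isa <- vals[keys == "is_a"]
    # strip trailing "! name" comments
    isa <- sub("\\s*!.*$", "", isa)
    isa <- trimws(isa)
    ids <- c(ids, id)
    nms <- c(nms, if (is.na(nm)) "" else nm)
    parents[[id]] <- unique(isa[nzchar(isa)])
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate term id in OBO file: ", dup)
  }
  names(nms) <- ids
  # drop links to obsolete or unknown parents (OBO files may dangle)
  parents <- lapply(parents, function(p) p[p %in% ids])
  roots <- ids[lengths(parents[ids]) == 0L]
  if (length(roots) == 0L)
    stop("structural error: ontology has no root (all terms have parents)")
  if (length(roots) > 1L)
    stop("structural error: multiple parentless terms: ",
         paste(utils::head(roots, 5), collapse = ", "))
  children <- invertParents(parents, ids)
  new("OntologyDAG", terms = ids, termNames = nms,
      parents = parents[ids], children = children, root = roots)
}

invertParents <- function(parents, ids) {
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) children[[id]] <- character(0)
  for (id in ids)
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  children
}

#' Compute term levels as shortest-path distance from the root
#'
#' Levels follow the convention that the root's children sit at level 1;
#' a multi-parent term takes the length of its SHORTEST upward path. A
#' cycle or a term unreachable from the root raises a structural error.
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @return the DAG with the \code{level} slot filled (root = 0).
#' @export
computeLevels <- function(dag) {
  stopifnot(is(dag, "OntologyDAG"))
  lev <- rep(NA_integer_, length(dag@terms))
  names(lev) <- dag@terms
  lev[dag@root] <- 0L
  frontier <- dag@root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(dag@children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lev[nxt])]
    lev[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(lev)) {
    stray <- names(lev)[is.na(lev)][1]
    stop("structural error: term unreachable from root (cycle or orphan): ",
         stray)
  }
  assertAcyclic(dag)
  dag@level <- lev
  validObject(dag)
  dag
}

# Kahn topological check; stops on a cycle.
assertAcyclic <- function(dag) {
  indeg <- lengths(dag@parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in dag@children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(dag@terms))
    stop("structural error: cycle detected in ontology graph")
  invisible(TRUE)
}

# All strict descendants of each term, memoized over a reverse
# topological order. Returns a named list of character vectors.
descendantSets <- function(dag) {
  lev <- dag@level
  if (!length(lev)) stop("call computeLevels() first")
  ord <- names(sort(lev, decreasing = TRUE))  # children before parents
  desc <- vector("list", length(ord))
  names(desc) <- ord
  for (t in ord) {
    kids <- dag@children[[t]]
    desc[[t]] <- if (length(kids))
      unique(c(kids, unlist(desc[kids], use.names = FALSE)))
    else character(0)
  }
  desc[dag@terms]
}

#' Annotated strict descendants of a term
#'
#' All strict descendants of \code{term} (reachable through any parent
#' path) that carry at least one annotation in \code{annotations}. Its
#' size is the count n_j behind the granularity weight.
#'
#' @param dag an \linkS4class{OntologyDAG} with levels computed.
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param term a term accession.
#' @return character vector of annotated descendant accessions.
#' @export
annotatedDescendants <- function(dag, annotations, term) {
  if (!term %in% dag@terms) stop("unknown term: ", term)
  annotated <- termIds(annotations)
  desc <- character(0)
  frontier <- dag@children[[term]]
  seen <- character(0)
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(dag@children[frontier], use.names = FALSE)
  }
  intersect(seen, annotated)
}

#' Granularity weight from an annotated-descendant count
#'
#' Maps the number n of annotated terms below a phenotype term to its
#' granularity weight. The default "inverse" scheme, g = 1 / (1 + n),
#' down-weights broad terms so that specific annotations dominate the
#' biadjacency matrix; the "linear" scheme, g = 1 + n, weights terms up
#' with the size of their annotated subtree instead. See the methods
#' vignette for the rationale behind shipping both.
#'
#' @param n non-negative integer count(s) of annotated descendants.
#' @param scheme "inverse" (default) or "linear".
#' @return positive numeric weight(s).
#' @examples
#' granularityWeight(9)            # 0.1
#' granularityWeight(3, "linear")  # 4
#' @export
granularityWeight <- function(n, scheme = c("inverse", "linear")) {
  scheme <- match.arg(scheme)
  if (any(n < 0)) stop("annotated-descendant count must be non-negative")
  if (scheme == "inverse") 1 / (1 + n) else 1 + n
}

#' Fill annotated-descendant counts and granularity weights
#'
#' Computes n_j (number of annotated strict descendants) for every term
#' against a fixed annotation set, then the granularity weight under the
#' chosen scheme. The scheme is recorded on the object.
#'
#' @inheritParams annotatedDescendants
#' @param scheme "inverse" or "linear"; see
#'   \code{\link{granularityWeight}}.
#' @return the DAG with \code{nAnnotatedBelow} and \code{granularity}
#'   slots filled.
#' @export
annotateGranularity <- function(dag, annotations,
                                scheme = c("inverse", "linear")) {
  scheme <- match.arg(scheme)
  if (!length(dag@level)) stop("call computeLevels() first")
  annotated <- termIds(annotations)
  desc <- descendantSets(dag)
  n <- vapply(desc, function(d) sum(d %in% annotated), 0L)
  dag@nAnnotatedBelow <- n
  dag@granularity <- granularityWeight(n, scheme)
  dag@granularityScheme <- scheme
  validObject(dag)
  dag
}

# Ancestor sets (strict, via any path), memoized top-down.
ancestorSets <- function(dag) {
  lev <- dag@level
  if (!length(lev)) stop("call computeLevels() first")
  ord <- names(sort(lev))  # parents before children
  anc <- vector("list", length(ord))
  names(anc) <- ord
  for (t in ord) {
    ps <- dag@parents[[t]]
    anc[[t]] <- if (length(ps))
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    else character(0)
  }
  anc[dag@terms]
}

#' Ancestors of a term at a target level
#'
#' All ancestors of \code{term} at exactly level \code{L}, reachable by
#' any upward path; the term itself is included when it already sits at
#' level L. Terms with multiple parents can return several ancestors,
#' which is what makes one annotation contribute to several biadjacency
#' columns. A term lying above level L yields an empty set.
#'
#' @inheritParams annotatedDescendants
#' @param L target level (>= 1).
#' @return character vector of level-L ancestor accessions.
#' @export
ancestorsAtLevel <- function(dag, term, L) {
  if (!term %in% dag@terms) stop("unknown term: ", term)
  stopifnot(L >= 1)
  lev <- dag@level
  if (!length(lev)) stop("call computeLevels() first")
  if (lev[term] < L) return(character(0))
  if (lev[term] == L) return(term)
  up <- term
  seen <- character(0)
  while (length(up)) {
    seen <- c(seen, up)
    up <- setdiff(unique(unlist(dag@parents[up], use.names = FALSE)), seen)
  }
  seen[lev[seen] == L]
}

# Level-L ancestors for every term in `terms`, as a named list.
ancestorsAtLevelMap <- function(dag, terms, L) {
  lev <- dag@level
  anc <- ancestorSets(dag)
  lapply(stats::setNames(terms, terms), function(t) {
    if (lev[t] == L) return(t)
    a <- anc[[t]]
    a[lev[a] == L]
  })
}

#' Histogram of annotation usage by ontology level
#'
#' Counts raw annotation records per level of their annotated term. The
#' mode of this histogram is the natural analysis level for the
#' biadjacency matrix (for mouse phenotype annotations the peak sits at
#' level 5).
#'
#' @inheritParams annotatedDescendants
#' @return named integer vector, level -> count; sums to the number of
#'   records whose terms are in the DAG.
#' @export
levelUsageHistogram <- function(dag, annotations) {
  if (!length(dag@level)) stop("call computeLevels() first")
  tt <- records(annotations)$term
  tt <- tt[tt %in% dag@terms]
  if (!length(tt)) return(stats::setNames(integer(0), character(0)))
  tab <- table(dag@level[tt])
  stats::setNames(as.integer(tab), names(tab))
}

#' Export the per-term level/weight table
#'
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @param path optional TSV output path.
#' @return data.frame(term, level, nAnnotatedBelow, granularity),
#'   invisibly when written to file.
#' @export
termTable <- function(dag, path = NULL) {
  df <- data.frame(term = dag@terms,
                   level = unname(dag@level[dag@terms]),
                   nAnnotatedBelow = if (length(dag@nAnnotatedBelow))
                     unname(dag@nAnnotatedBelow[dag@terms]) else NA_integer_,
                   granularity = if (length(dag@granularity))
                     unname(dag@granularity[dag@terms]) else NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    writeTsv(df, path)
    return(invisible(df))
  }
  df
}
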