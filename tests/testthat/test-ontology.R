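test_that("OBO parsing builds the DAG, drops obsolete terms, flags errors", {
  dag <- chainDag()
  expect_s4_class(dag, "OntologyDAG")
  expect_setequal(termIds(dag), c("T:0", "T:A", "T:B"))
  expect_identical(dag@parents[["T:B"]], "T:A")
  expect_identical(dag@root, "T:0")

  # stanza with two is_a lines -> two parents
  dd <- diamondDag()
  expect_setequal(dd@parents[["T:C"]], c("T:A", "T:B"))

  # obsolete terms excluded (and links to them pruned)
  f <- writeOboFile(oboTerm("T:0", "root"),
                    oboTerm("T:A", "a", "T:0"),
                    oboTerm("T:X", "gone", "T:0", obsolete = TRUE),
                    oboTerm("T:B", "b", "T:A"))
  dag2 <- parseOBO(f)
  expect_setequal(termIds(dag2), c("T:0", "T:A", "T:B"))

  # malformed stanza names the line; missing root is structural
  bad <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: T:0",
               "name: root", "", "[Term]", "id T:1 broken"), bad)
  expect_error(parseOBO(bad), "malformed stanza")
  cyc <- writeOboFile(oboTerm("T:A", "a", "T:B"),
                      oboTerm("T:B", "b", "T:A"))
  expect_error(parseOBO(cyc), "no root")
  multi <- writeOboFile(oboTerm("T:0", "r1"), oboTerm("T:1", "r2"))
  expect_error(parseOBO(multi), "multiple parentless")
})

test_that("levels are shortest-path distances from the root", {
  dag <- chainDag()
  expect_identical(unname(termLevels(dag)[c("T:A", "T:B")]), c(1L, 2L))

  # diamond: C reachable at depth 2 by both paths
  dd <- diamondDag()
  expect_identical(unname(termLevels(dd)["T:C"]), 2L)

  # shortest path wins for multi-parent terms: root->A->C and root->C'
  f <- writeOboFile(oboTerm("T:0", "root"),
                    oboTerm("T:A", "a", "T:0"),
                    oboTerm("T:B", "b", "T:A"),
                    oboTerm("T:C", "c", c("T:B", "T:0")))
  dag3 <- computeLevels(parseOBO(f))
  expect_identical(unname(termLevels(dag3)["T:C"]), 1L)
})

test_that("levels on random DAGs equal independent BFS distances", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 200
    ids <- sprintf("T:%03d", seq_len(n))
    parents <- vector("list", n)
    names(parents) <- ids
    parents[[1]] <- character(0)
    for (i in 2:n) {
      nPar <- 1L + stats::rbinom(1, 1, 0.15)
      parents[[i]] <- ids[sample.int(i - 1L, min(nPar, i - 1L))]
    }
    f <- writeOboFile(unlist(lapply(seq_len(n), function(i)
      oboTerm(ids[i], isa = parents[[i]]))))
    dag <- computeLevels(parseOBO(f))
    # oracle: igraph shortest paths on the child-ward edge list
    el <- do.call(rbind, lapply(ids, function(id)
      if (length(parents[[id]]))
        cbind(parents[[id]], id) else NULL))
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    dist <- igraph::distances(g, v = "T:001", mode = "out")[1, ]
    expect_identical(unname(termLevels(dag)[names(dist)]),
                     as.integer(dist))
  }
})

test_that("annotated descendant counts follow set semantics", {
  # leaf -> empty set
  dag <- chainDag()
  ann <- makeAnnotations(c("g1", "g2"), c("T:A", "T:B"))
  expect_length(annotatedDescendants(dag, ann, "T:B"), 0)

  # root with annotated leaves below, counted by exhaustive traversal
  f <- writeOboFile(oboTerm("T:0", "root"),
                    oboTerm("T:M", "mid", "T:0"),
                    unlist(lapply(paste0("T:L", 1:5), oboTerm,
                                  isa = "T:M")))
  dag2 <- computeLevels(parseOBO(f))
  ann2 <- makeAnnotations(paste0("g", 1:5), paste0("T:L", 1:5))
  expect_setequal(annotatedDescendants(dag2, ann2, "T:0"),
                  paste0("T:L", 1:5))
  expect_length(annotatedDescendants(dag2, ann2, "T:0"), 5)

  # multi-parent descendant counted once
  dd <- diamondDag()
  annd <- makeAnnotations("g1", "T:C")
  expect_identical(annotatedDescendants(dd, annd, "T:0"), "T:C")
  expect_error(annotatedDescendants(dd, annd, "T:missing"), "unknown")
})

test_that("granularity weights follow the configured scheme", {
  expect_identical(granularityWeight(0), 1)
  expect_identical(granularityWeight(9), 0.1)
  expect_identical(granularityWeight(3, "linear"), 4)
  expect_error(granularityWeight(-1), "non-negative")

  dag <- diamondDag()
  ann <- makeAnnotations("g1", "T:C")
  dag <- annotateGranularity(dag, ann)
  expect_identical(unname(dag@nAnnotatedBelow[c("T:0", "T:A", "T:C")]),
                   c(1L, 1L, 0L))
  expect_identical(unname(granularity(dag)[c("T:A", "T:C")]),
                   c(0.5, 1))
})

test_that("n_j is monotone non-decreasing from leaves to root", {
  b <- smallBundle()
  dag <- annotateGranularity(b$dag, b$annotations)
  n <- dag@nAnnotatedBelow
  for (tm in termIds(dag)) {
    for (p in dag@parents[[tm]]) {
      expect_gte(n[[p]], n[[tm]])
    }
  }
})

test_that("ancestors at a level handle self, diamonds, and depth", {
  dd <- diamondDag()
  # self inclusion at the target level
  expect_identical(ancestorsAtLevel(dd, "T:A", 1L), "T:A")
  # diamond ancestry: both level-1 ancestors returned
  expect_setequal(ancestorsAtLevel(dd, "T:C", 1L), c("T:A", "T:B"))
  # term above the target level -> empty
  expect_length(ancestorsAtLevel(dd, "T:A", 2L), 0)
  expect_error(ancestorsAtLevel(dd, "nope", 1L), "unknown")

  # on a tree every deep-enough term has exactly one level-L ancestor
  b <- smallBundle()
  dag <- b$dag
  deep <- termIds(dag)[termLevels(dag) >= 3]
  set.seed(5)
  nChecked <- 0L
  for (tm in sample(deep, 40)) {
    cur <- tm
    pureLineage <- TRUE
    while (cur != dag@root) {
      ps <- dag@parents[[cur]]
      if (length(ps) != 1L) { pureLineage <- FALSE; break }
      cur <- ps
    }
    if (!pureLineage) next
    expect_length(ancestorsAtLevel(dag, tm, 2L), 1)
    nChecked <- nChecked + 1L
  }
  expect_gt(nChecked, 5)
})

test_that("level usage histogram counts every record at its term level", {
  f <- writeOboFile(oboTerm("T:0", "root"),
                    oboTerm("T:A", "a", "T:0"),
                    oboTerm("T:B", "b", "T:A"),
                    oboTerm("T:C", "c", "T:B"))
  dag <- computeLevels(parseOBO(f))
  ann <- makeAnnotations(paste0("g", 1:4),
                         c("T:A", "T:B", "T:B", "T:C"))
  h <- levelUsageHistogram(dag, ann)
  expect_identical(h, stats::setNames(c(1L, 2L, 1L), c("1", "2", "3")))
  expect_identical(sum(h), nrow(records(ann)))
  empty <- levelUsageHistogram(dag, makeAnnotations(character(0),
                                                   character(0)))
  expect_length(empty, 0)
})

test_that("synthetic OBO round-trips losslessly through the parser", {
  b <- smallBundle()
  dag <- b$dag
  raw <- readLines(b$paths$ontology)
  expect_identical(length(termIds(dag)), sum(raw == "[Term]"))
  expect_identical(sum(lengths(dag@parents)),
                   length(grep("^is_a:", raw)))
})
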