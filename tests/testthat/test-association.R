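makeAssoc <- function(m, kind = "gene", level = 1L) {
  new("AssociationMatrix", values = m, kind = kind,
      level = as.integer(level), perFeature = phenonet:::emptyPerFeature())
}

# Exhaustive permutation two-sided rank-sum p (midranks), the
# independent oracle for small samples.
enumRankSumP <- function(u, v) {
  z <- c(u, v); n1 <- length(u); n <- length(z)
  r <- rank(z)
  wObs <- sum(r[seq_len(n1)])
  sel <- utils::combn(n, n1)
  ws <- apply(sel, 2, function(ix) sum(r[ix]))
  ew <- mean(ws)
  mean(abs(ws - ew) >= abs(wObs - ew) - 1e-9)
}

test_that("the rank-sum p-value matches wilcox.test across regimes", {
  set.seed(99)
  for (i in 1:40) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    u <- round(stats::runif(n1), sample(c(1, 3), 1))  # ties when rounded
    v <- round(stats::runif(n2), sample(c(1, 3), 1))
    # align the exact-test size threshold with wilcox.test's for the
    # comparison (the package default switches to the approximation
    # earlier, at 10 per side)
    got <- phenonet:::rankSumP(u, v, exactMax = 49L)
    want <- suppressWarnings(stats::wilcox.test(u, v)$p.value)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # large samples route through the normal approximation
  u <- stats::rnorm(60); v <- stats::rnorm(55) + 0.3
  expect_equal(phenonet:::rankSumP(u, v),
               suppressWarnings(stats::wilcox.test(u, v)$p.value),
               tolerance = 1e-10)
  expect_error(phenonet:::rankSumP(numeric(0), 1), "non-empty")
})

test_that("per-phenotype scores: identity, disparity, no-signal", {
  dag <- local({
    f <- writeOboFile(oboTerm("T:0", "root"),
                      oboTerm("T:P", "p", "T:0"),
                      oboTerm("T:Q", "q", "T:0"),
                      unlist(lapply(sprintf("T:p%d", 1:5), oboTerm,
                                    isa = "T:P")),
                      oboTerm("T:q1", "q1", "T:Q"))
    computeLevels(parseOBO(f))
  })
  ann <- makeAnnotations(
    c(rep("G1", 5), rep("G2", 5), "G3"),
    c(sprintf("T:p%d", 1:5), sprintf("T:p%d", 1:5), "T:q1"))
  dag <- annotateGranularity(dag, ann)
  B <- buildBiadjacency(ann, dag, 1L)

  # identical profiles -> maximal similarity p = 1
  expect_identical(pairPhenotypeScore(B, "G1", "G2", "T:P"), 1)

  # fully annotated vs unannotated: small p, near the exact
  # permutation oracle (u = five equal weights, v = five zeros)
  pGot <- pairPhenotypeScore(B, "G1", "G3", "T:P")
  w <- granularity(dag)["T:p1"]
  pExact <- enumRankSumP(rep(w, 5), rep(0, 5))
  expect_lt(pGot, 0.05)
  expect_lt(abs(pGot - pExact), 0.02)

  # neither annotated under the column -> no-signal sentinel
  expect_true(is.na(pairPhenotypeScore(B, "G1", "G2", "T:Q")))
  expect_error(pairPhenotypeScore(B, "G1", "G1", "T:P"))
  expect_error(pairPhenotypeScore(B, "G1", "G2", "T:missing"),
               "unknown")
})

test_that("BH correction is monotone with the hand-checked example", {
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_identical(fdrCorrect(0.2), 0.2)
  expect_identical(fdrCorrect(rep(1, 5)), rep(1, 5))
  expect_error(fdrCorrect(numeric(0)), "empty")
  expect_error(fdrCorrect(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- stats::runif(200)
  q <- fdrCorrect(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_identical(fdrCorrect(p, method = "none"), p)
})

test_that("d aggregates corrected similarity over all columns", {
  # ten level-1 groups, each with one leaf; G3 annotated everywhere,
  # G1 and G2 identically in the first three groups
  blocks <- unlist(lapply(1:10, function(i)
    c(oboTerm(sprintf("T:G%02d", i), isa = "T:0"),
      oboTerm(sprintf("T:g%02d", i), isa = sprintf("T:G%02d", i)))))
  f <- writeOboFile(oboTerm("T:0", "root"), blocks)
  dag <- computeLevels(parseOBO(f))
  ann <- makeAnnotations(
    c(rep("G1", 3), rep("G2", 3), rep("G3", 10)),
    c(sprintf("T:g%02d", 1:3), sprintf("T:g%02d", 1:3),
      sprintf("T:g%02d", 1:10)))
  dag <- annotateGranularity(dag, ann)
  B <- buildBiadjacency(ann, dag, 1L)
  expect_identical(ncol(values(B)), 10L)
  A <- associationMatrix(B)
  # identical genes, q = 1 on each of the 3 shared columns of 10
  expect_equal(values(A)["G1", "G2"], 0.3)
  expect_equal(values(A)["G1", "G3"], 0.3)  # same leaves shared

  # d recomputed independently from the per-feature table
  A2 <- associationMatrix(B, keepPerFeature = TRUE)
  pf <- A2@perFeature
  for (pr in list(c("G1", "G2"), c("G1", "G3"))) {
    dHand <- sum(pf$q[(pf$a == pr[1] & pf$b == pr[2]) |
                      (pf$a == pr[2] & pf$b == pr[1])]) / 10
    expect_equal(values(A2)[pr[1], pr[2]], dHand)
  }
})

test_that("d is a symmetric, bounded score vanishing without shared columns", {
  an <- plantedAnalysis()
  v <- values(an$A)
  expect_identical(v, t(v))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diag(v) == 0))
  # genes sharing no level-L phenotype have d exactly 0
  M <- values(an$B) > 0
  share <- tcrossprod(M * 1) > 0
  expect_true(all(v[!share] == 0))
})

test_that("annotation-identical genes achieve the maximal d", {
  set.seed(17)
  for (rep in 1:10) {
    # random fixture with a planted identical pair
    nG <- 8; nT <- 6
    blocks <- unlist(lapply(1:nT, function(i)
      c(oboTerm(sprintf("T:G%02d", i), isa = "T:0"),
        oboTerm(sprintf("T:g%02d", i), isa = sprintf("T:G%02d", i)))))
    f <- writeOboFile(oboTerm("T:0", "root"), blocks)
    dag <- computeLevels(parseOBO(f))
    gene <- character(0); term <- character(0)
    for (g in seq_len(nG)) {
      picks <- sample(nT, sample(2:4, 1))
      gene <- c(gene, rep(sprintf("G%d", g), length(picks)))
      term <- c(term, sprintf("T:g%02d", picks))
    }
    # G twin copies G1's annotations exactly
    g1 <- term[gene == "G1"]
    gene <- c(gene, rep("GT", length(g1)))
    term <- c(term, g1)
    ann <- makeAnnotations(gene, term)
    dag <- annotateGranularity(dag, ann)
    A <- associationMatrix(buildBiadjacency(ann, dag, 1L))
    v <- values(A)
    expect_gte(v["G1", "GT"] + 1e-12,
               max(v["G1", setdiff(rownames(v), "G1")]))
  }
})

test_that("the phenotype pipeline is the gene pipeline on the transpose", {
  an <- plantedAnalysis()
  Ap <- associationMatrix(t(an$B))
  expect_identical(Ap@kind, "phenotype")
  vp <- values(Ap)
  expect_identical(vp, t(vp))
  expect_true(all(vp >= 0 & vp <= 1))
  expect_identical(rownames(vp), colnames(values(an$B)))
  # term pairs sharing no annotated gene score 0
  M <- t(values(an$B)) > 0
  share <- tcrossprod(M * 1) > 0
  expect_true(all(vp[!share] == 0))
  # double transpose reproduces the gene matrix exactly
  expect_identical(values(associationMatrix(t(t(an$B)))),
                   values(an$A))
})

test_that("networks retain edges at or above the cutoff", {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 0.9
  m["A", "C"] <- m["C", "A"] <- 0.7
  m["B", "C"] <- m["C", "B"] <- 0.6
  m["C", "D"] <- m["D", "C"] <- 0.2
  A <- makeAssoc(m)
  net <- buildNetwork(A, 0.5)
  expect_identical(nrow(edges(net)), 3L)
  expect_false("D" %in% nodeIds(net))  # isolated after thresholding
  expect_true(all(edges(net)$weight >= 0.5))
  expect_true(all(edges(net)$from < edges(net)$to))

  # cutoff 0 keeps the complete weighted graph over connected nodes
  net0 <- buildNetwork(A, 0)
  expect_identical(nrow(edges(net0)), 4L)
  expect_warning(empty <- buildNetwork(A, 0.95), "no edges")
  expect_length(nodeIds(empty), 0)

  # shipped defaults are the published cut-offs
  rc <- referenceCutoffs()
  expect_identical(rc$dCutoff[rc$kind == "gene" & rc$level == 5], 0.009)
  expect_identical(rc$dCutoff[rc$kind == "gene" & rc$level == 8], 0.011)
  expect_identical(rc$dCutoff[rc$kind == "phenotype" & rc$level == 5],
                   0.005)
  expect_identical(rc$dCutoff[rc$kind == "phenotype" & rc$level == 8],
                   0.002)
})

test_that("suggested cutoffs track the nonzero-score distribution", {
  m <- matrix(0, 21, 21,
              dimnames = list(paste0("g", 1:21), paste0("g", 1:21)))
  grid <- seq(0.005, 1, length.out = 210)
  m[upper.tri(m)] <- grid
  m <- pmax(m, t(m))
  diag(m) <- 0
  A <- makeAssoc(m)
  expect_equal(suggestCutoff(A, 0.9),
               unname(stats::quantile(grid, 0.9)))
  mConst <- matrix(0.42, 3, 3,
                   dimnames = list(letters[1:3], letters[1:3]))
  diag(mConst) <- 0
  expect_equal(suggestCutoff(makeAssoc(mConst), 0.5), 0.42)
  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(suggestCutoff(makeAssoc(zero), 0.9), "no nonzero")

  # on planted data the suggested cutoff separates modules
  an <- plantedAnalysis()
  mod <- an$bundle$modules[rownames(values(an$A))]
  v <- values(an$A)
  same <- outer(mod, mod, "==") & upper.tri(v)
  cut <- suggestCutoff(an$A, 0.8)
  expect_gt(mean(v[same] >= cut), 0.5)       # most within-module pairs
  expect_lt(mean(v[!same & upper.tri(v)] >= cut), 0.02)
})

test_that("network exports round-trip and reach external formats", {
  an <- plantedAnalysis()
  f <- tempfile(fileext = ".tsv")
  exportNetwork(an$net, f)
  back <- phenonet:::readTsv(f)
  expect_identical(nrow(back), nrow(edges(an$net)))
  g <- tempfile(fileext = ".graphml")
  exportNetwork(an$net, g, format = "graphml")
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gg), length(nodeIds(an$net)))
  expect_equal(igraph::ecount(gg), nrow(edges(an$net)))
})
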