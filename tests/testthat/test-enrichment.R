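symMat <- function(n, fill, ids = sprintf("g%02d", seq_len(n))) {
  m <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

makePartition <- function(labels) {
  new("Partition", labels = labels, Q = NA_real_, method = "fixture",
      refined = FALSE)
}

test_that("within-community pooling enumerates unordered member pairs", {
  m <- symMat(5, 0.3)
  m["g01", "g02"] <- m["g02", "g01"] <- 0.9
  part <- makePartition(stats::setNames(c(1L, 1L, 1L, 2L, 3L),
                                        sprintf("g%02d", 1:5)))
  vals <- withinCommunityValues(part, m)
  expect_length(vals, 3)  # choose(3, 2)
  expect_setequal(round(vals, 2), c(0.9, 0.3, 0.3))
  # singletons contribute nothing
  solo <- makePartition(stats::setNames(1:2, c("g01", "g04")))
  expect_length(withinCommunityValues(solo, m), 0)
  # nodes missing from the matrix are skipped and counted
  part2 <- makePartition(stats::setNames(c(1L, 1L, 1L),
                                         c("g01", "g02", "zz")))
  v2 <- withinCommunityValues(part2, m)
  expect_length(v2, 1)
  expect_identical(attr(v2, "nMissing"), 1L)
})

test_that("resampled controls are reproducible and unbiased", {
  m <- symMat(20, 0.25)
  set.seed(1)
  a <- resampledControl(c(4L, 3L), rownames(m), m, nBoot = 5L,
                        seed = 11L)
  b <- resampledControl(c(4L, 3L), rownames(m), m, nBoot = 5L,
                        seed = 11L)
  expect_identical(a, b)
  # uniform off-diagonal matrix: control values equal the constant
  expect_true(all(a == 0.25))
  expect_error(resampledControl(25L, rownames(m), m, 2L, seed = 1L),
               "universe")
})

test_that("distribution comparison is one-sided in the right direction", {
  set.seed(2)
  x <- stats::rnorm(200)
  expect_gt(compareDistributions(x, x + stats::rnorm(200, 0, 1e-8)), 0.3)
  expect_lt(compareDistributions(x + 2, x), 1e-10)
  expect_gt(compareDistributions(x - 2, x), 0.999)
  expect_error(compareDistributions(numeric(0), x), "non-empty")
})

test_that("planted coexpression and profile similarity enrich communities", {
  an <- plantedAnalysis()
  b <- an$bundle
  part <- an$part
  for (spec in list(list(m = pairwiseCorrelation(b$expression),
                         metric = "expr_corr"),
                    list(m = pairwiseCorrelation(b$tissue),
                         metric = "tissue_corr"),
                    list(m = pairwiseCorrelation(b$phylo),
                         metric = "phylo_corr"))) {
    res <- communityEnrichment(part, spec$m, spec$metric,
                               nBoot = 100L, seed = 7L)
    expect_lt(res@pValue, 0.001)
    expect_gt(mean(res@within), mean(res@control))
  }
  # correlation of a profile with itself is 1
  expect_equal(unname(diag(pairwiseCorrelation(b$expression))),
               rep(1, nrow(b$expression)))
})

test_that("PPI parsing keeps only physical evidence", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\tTwo-Hybrid",
               "g2\tg3\tDosage Rescue",
               "g3\tg1\tReconstituted Complex",
               "g1\tg1\tTwo-Hybrid",
               "g2\tg1\tTwo-Hybrid"), f)
  ppi <- readPPI(f)
  expect_identical(nrow(ppi), 2L)  # decoy dropped, self + dup removed
  expect_setequal(paste(ppi$a, ppi$b), c("g1 g2", "g1 g3"))
  expect_length(physicalEvidenceTypes(), 14)
  expect_true(all(c("Two-Hybrid", "Affinity Capture-MS",
                    "Reconstituted Complex") %in%
                  physicalEvidenceTypes()))
  expect_false("Dosage Rescue" %in% physicalEvidenceTypes())
})

test_that("within-community interaction counts exceed resampled nulls", {
  an <- plantedAnalysis()
  b <- an$bundle
  ppi <- b$ppi[b$ppi$evidence %in% physicalEvidenceTypes(), c("a", "b")]
  res <- ppiCountEnrichment(an$part, ppi, nBoot = 100L, seed = 19L)
  expect_lt(res@pValue, 0.01)
  expect_gt(res@within[1], mean(res@control))

  # interactions disjoint from the communities: observed 0, p undefined
  far <- data.frame(a = c("x1", "x2"), b = c("x2", "x3"))
  expect_warning(r0 <- ppiCountEnrichment(an$part, far, nBoot = 10L,
                                          seed = 1L), "no interaction")
  expect_true(is.na(r0@pValue))
})

test_that("GO similarity d enriches planted modules at the set levels", {
  an <- plantedAnalysis()
  res <- goSimilarityD(an$part, an$bundle$goAnnotations,
                       an$bundle$goDags, nBoot = 100L, seed = 23L)
  expect_setequal(names(res), c("BP", "CC", "MF"))
  for (r in res) expect_lt(r@pValue, 0.001)
  # default analysis levels follow each branch's annotation peak
  expect_identical(formals(goSimilarityD)$levels,
                   quote(c(BP = 5L, CC = 5L, MF = 2L)))
})

test_that("hub GO over-representation matches the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:40)
  hubs <- universe[1:8]
  # term A in every hub and nowhere else; term B spread evenly
  ann <- makeAnnotations(
    c(hubs, universe[seq(1, 40, by = 4)]),
    c(rep("GO:A", 8), rep("GO:B", 10)))
  tab <- hubGOFisher(hubs, universe, ann)
  a <- tab[tab$term == "GO:A", ]
  # oracle: exact hypergeometric upper tail for 8 of 8 hub draws
  pOracle <- stats::phyper(7, 8, 32, 8, lower.tail = FALSE)
  expect_equal(a$p, pOracle, tolerance = 1e-12)
  expect_identical(tab$term[1], "GO:A")  # top-ranked
  b <- tab[tab$term == "GO:B", ]
  expect_gt(b$p, 0.3)  # proportional spread is unremarkable
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_error(hubGOFisher(c("zz"), universe, ann))
})

test_that("a planted regulator term tops the hub enrichment", {
  an <- plantedAnalysis()
  net <- an$net
  hubs <- hubNodes(net)
  expect_gt(length(hubs), 0)
  expect_lte(length(hubs), ceiling(0.25 * length(nodeIds(net))))
  # plant a term annotating exactly the hubs, among background terms
  set.seed(3)
  bg <- sprintf("GO:bg%02d", 1:5)
  ann <- makeAnnotations(
    c(hubs, sample(nodeIds(net), 120, replace = TRUE)),
    c(rep("GO:reg", length(hubs)),
      sample(bg, 120, replace = TRUE)))
  tab <- hubGOFisher(hubs, nodeIds(net), ann)
  expect_identical(tab$term[1], "GO:reg")
  expect_lt(tab$q[1], 0.001)
})

test_that("level-1 term sharing yields the 3-dof contingency test", {
  an <- plantedAnalysis()
  ct <- level1SharingChisq(an$part, an$B1)
  expect_identical(ct@dof, 3L)
  expect_identical(dim(ct@table), c(2L, 4L))
  expect_lt(ct@p, 0.001)
  expect_gt(ct@fracSameWithin, ct@fracSameOverall)

  # all genes share all terms: fractions 1, chi-square 0
  m <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4),
                                       paste0("t", 1:3)))
  B1 <- makeBiadjacency(m)
  part <- makePartition(stats::setNames(c(1L, 1L, 2L, 2L),
                                        paste0("g", 1:4)))
  ct0 <- level1SharingChisq(part, B1)
  expect_equal(ct0@chiSq, 0)
  expect_identical(ct0@fracSameWithin, 1)
  expect_identical(ct0@fracSameOverall, 1)

  # hand-computed fixture: shared counts and the chi-square statistic
  m2 <- rbind(g1 = c(1, 1, 0), g2 = c(1, 1, 0), g3 = c(0, 0, 1),
              g4 = c(0, 1, 1))
  colnames(m2) <- paste0("t", 1:3)
  part2 <- makePartition(stats::setNames(c(1L, 1L, 2L, 2L),
                                         paste0("g", 1:4)))
  ct2 <- level1SharingChisq(part2, makeBiadjacency(m2))
  shared <- tcrossprod(m2)  # pairwise shared-term counts
  ut <- upper.tri(shared)
  expect_equal(ct2@fracSameOverall, mean(shared[ut] >= 1))
  within <- shared[cbind(c(1, 3), c(2, 4))]
  expect_equal(ct2@fracSameWithin, mean(within >= 1))
  expect_error(level1SharingChisq(makePartition(
    stats::setNames(integer(0), character(0))), makeBiadjacency(m2)),
    "no communities")
})
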