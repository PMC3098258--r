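# Exhaustive enumeration oracle over all subset pairs of an N universe.
enumIntersection <- function(N, x, y) {
  xs <- utils::combn(N, x, simplify = FALSE)
  ys <- utils::combn(N, y, simplify = FALSE)
  zs <- unlist(lapply(xs, function(a)
    vapply(ys, function(b) length(intersect(a, b)), 0L)))
  tabulate(zs + 1L, nbins = min(x, y) + 1L) / length(zs)
}

test_that("the intersection pmf matches exhaustive enumeration (N <= 8)", {
  for (N in 2:8) {
    for (x in 1:N) {
      for (y in 1:N) {
        want <- enumIntersection(N, x, y)
        got <- intersectionPmf(N, x, y, 0:min(x, y))
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
  # the worked small case: N=4, x=2, y=2
  expect_equal(intersectionPmf(4, 2, 2, 0:2), c(1, 4, 1) / 6)
  # infeasible intersections have probability zero
  expect_identical(intersectionPmf(10, 3, 4, 5), 0)
  expect_identical(intersectionPmf(10, 8, 8, 2), 0)  # y-z > N-x
})

test_that("the pmf normalizes and has mean xy/N", {
  for (N in c(5L, 12L, 30L)) {
    for (x in c(2L, N %/% 2, N - 1L)) {
      for (y in c(1L, N %/% 3 + 1L, N - 2L)) {
        z <- 0:min(x, y)
        p <- intersectionPmf(N, x, y, z)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_equal(sum(z * p), x * y / N, tolerance = 1e-12)
      }
    }
  }
})

test_that("tail probabilities accumulate the pmf upper tail", {
  expect_identical(intersectionTailP(10, 4, 5, 0), 1)
  # equals the pmf at the maximal nested point
  expect_equal(intersectionTailP(6, 2, 4, 2),
               intersectionPmf(6, 2, 4, 2), tolerance = 1e-12)
  # matches Monte-Carlo draws within 3 standard errors (N=20, x=y=5)
  set.seed(12)
  nDraw <- 2e5
  z <- replicate(nDraw, {
    length(intersect(sample.int(20, 5), sample.int(20, 5)))
  })
  pHat <- mean(z >= 4)
  se <- sqrt(pHat * (1 - pHat) / nDraw)
  expect_lt(abs(intersectionTailP(20, 5, 5, 4) - pHat), 3 * se + 1e-6)
  # tail is a decreasing step function of z_obs
  tails <- vapply(0:5, function(zz) intersectionTailP(20, 5, 5, zz), 0)
  expect_true(all(diff(tails) <= 1e-12))
})

test_that("overlap fractions average the two containment fractions", {
  expect_identical(overlapFraction(letters[1:4], letters[1:4]), 1)
  expect_identical(overlapFraction(letters[1:3], letters[5:7]), 0)
  expect_identical(overlapFraction(letters[1:4], letters[1:2]), 0.75)
  expect_identical(overlapFraction(letters[1:2], letters[1:4]), 0.75)
  expect_error(overlapFraction(character(0), "a"), "non-empty")
})

test_that("highest-scoring level-1 assignment handles argmax, ties, zeros", {
  m <- rbind(g1 = c(0.2, 0.9, 0.1), g2 = c(0.5, 0.5, 0),
             g3 = c(0, 0, 0))
  colnames(m) <- paste0("t", 1:3)
  B1 <- makeBiadjacency(m)
  hs <- highestScoringLevel1(B1)
  expect_identical(unname(hs["g1"]), "t2")
  expect_identical(unname(hs["g2"]), "<tie>")
  expect_true(is.na(hs["g3"]))
  expect_identical(unname(highestScoringLevel1(B1, "g1")), "t2")
  expect_error(highestScoringLevel1(B1, "zz"), "unknown")
})

test_that("cross-partition overlap matrices behave in both modes", {
  lab <- stats::setNames(rep(1:3, each = 4), sprintf("g%02d", 1:12))
  part <- new("Partition", labels = lab, Q = NA_real_,
              method = "fixture", refined = FALSE)
  self <- crossPartitionMatrix(part, part, mode = "fraction")
  expect_equal(unname(diag(values(self))), rep(1, 3))
  expect_true(all(values(self)[upper.tri(values(self))] == 0))

  # disjoint universes are an error
  lab2 <- stats::setNames(rep(1:2, each = 3), sprintf("h%02d", 1:6))
  part2 <- new("Partition", labels = lab2, Q = NA_real_,
               method = "fixture", refined = FALSE)
  expect_error(crossPartitionMatrix(part, part2), "share no nodes")

  # orthology map translates the second partition's namespace
  idMap <- data.frame(from = sprintf("h%02d", 1:6),
                      to = sprintf("g%02d", 1:6))
  om <- crossPartitionMatrix(part, part2, idMap = idMap,
                             mode = "fraction")
  # universe shrinks to g01..g06; h01..h03 map into community A1
  expect_equal(values(om)["A1", "B1"], (3 / 4 + 1) / 2)
  expect_equal(values(om)["A2", "B1"], 0)

  # a planted shared module dominates both modes
  labA <- stats::setNames(rep(1:2, each = 10), sprintf("g%02d", 1:20))
  labB <- labA
  labB[11:20] <- sample(rep(3:4, each = 5))  # scramble second half
  partA <- new("Partition", labels = labA, Q = NA_real_,
               method = "fixture", refined = FALSE)
  partB <- new("Partition", labels = labB, Q = NA_real_,
               method = "fixture", refined = FALSE)
  for (mode in c("tail_p", "fraction")) {
    omp <- crossPartitionMatrix(partA, partB, mode = mode)
    v <- values(omp)
    expect_identical(unname(which.max(v["A1", ])),
                     which(colnames(v) == "B1"))
    expect_identical(unname(which.max(v[, "B1"])),
                     which(rownames(v) == "A1"))
  }
})

test_that("communities map onto their planted level-1 groups", {
  an <- plantedAnalysis()
  cg <- communityGroupMatrix(an$part, an$B1, cluster = FALSE)
  v <- values(cg)
  # each community's best group should be its module subtree's
  # level-1 term, scored far beyond chance
  lab <- communityLabels(an$part)
  mod <- an$bundle$modules
  hits <- 0L
  for (cm in sort(unique(lab))) {
    members <- names(lab)[lab == cm]
    plantedMod <- as.integer(names(which.max(table(mod[members]))))
    best <- colnames(v)[which.max(v[paste0("C", cm), ])]
    # group term of the planted module: the subtree's level-1 root
    lead <- names(which.max(table(
      highestScoringLevel1(an$B1)[members])))
    if (identical(best, lead)) hits <- hits + 1L
    expect_gt(max(v[paste0("C", cm), ]), -log10(0.001))
  }
  expect_gte(hits, length(unique(lab)) - 1L)
  f <- tempfile(fileext = ".tsv")
  writeOverlapMatrix(cg, f)
  expect_identical(dim(phenonet:::readMatrixTsv(f)), dim(v))
})
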