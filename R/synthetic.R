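# Self-contained synthetic inputs with planted module structure: a
# rooted DAG ontology with occasional multi-parent terms, gene modules
# preferentially annotated under distinct level-1 subtrees, within-
# module correlated expression, module-biased tissue expression,
# module-enriched protein interactions, module-correlated phylogenetic
# profiles and module-coherent GO annotation. Every pipeline stage is
# testable against the emitted planted labels.

#' Configuration for the synthetic planted-module generator
#'
#' Defaults are sized for desk analyses: 300 genes in 5 modules over a
#' depth-8 ontology of ~2000 terms, with annotation levels peaking
#' mid-ontology the way curated phenotype annotation does. Fidelity is
#' the probability that an annotation falls inside the gene's module
#' subtree; the pleiotropy noise rate adds uniformly placed extra
#' annotations. See the methods vignette for what each knob emulates.
#'
#' @param seed RNG seed (mandatory).
#' @param nGenes,nModules gene count and planted module count.
#' @param ontologyDepth maximum term level of the phenotype ontology.
#' @param rootBranching number of level-1 subtrees (must be >= nModules).
#' @param branching children per internal term below level 1.
#' @param multiParentRate fraction of deep terms given a second parent.
#' @param perGeneMean mean phenotype annotations per gene (Poisson).
#' @param moduleFidelity probability an annotation stays in-module.
#' @param pleiotropyNoiseRate per-annotation rate of extra uniform
#'   annotations anywhere in the ontology.
#' @param exprSamples,exprWithinCorr expression matrix: sample count and
#'   within-module Pearson correlation of the shared-factor model.
#' @param nTissues,tissueBias binary tissue matrix: tissue count and
#'   expression probability in module-preferred tissues (background 0.1).
#' @param ppiWithinDensity,ppiBetweenDensity interaction probability for
#'   within- and between-module gene pairs.
#' @param phyloSpecies,phyloWithinCorr phylogenetic profiles: species
#'   count and probability of copying the module base profile.
#' @param goFidelity module fidelity of the GO annotations.
#' @param goPerGeneMean mean GO annotations per gene per branch.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(seed, nGenes = 300L, nModules = 5L,
                            ontologyDepth = 8L, rootBranching = 8L,
                            branching = 2L, multiParentRate = 0.03,
                            perGeneMean = 8, moduleFidelity = 0.9,
                            pleiotropyNoiseRate = 0.05,
                            exprSamples = 50L, exprWithinCorr = 0.6,
                            nTissues = 30L, tissueBias = 0.8,
                            ppiWithinDensity = 0.15,
                            ppiBetweenDensity = 0.01,
                            phyloSpecies = 40L, phyloWithinCorr = 0.7,
                            goFidelity = 0.9, goPerGeneMean = 4) {
  if (missing(seed)) stop("seed is mandatory")
  p <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
            nModules = as.integer(nModules),
            ontologyDepth = as.integer(ontologyDepth),
            rootBranching = as.integer(rootBranching),
            branching = as.integer(branching),
            multiParentRate = multiParentRate,
            perGeneMean = perGeneMean, moduleFidelity = moduleFidelity,
            pleiotropyNoiseRate = pleiotropyNoiseRate,
            exprSamples = as.integer(exprSamples),
            exprWithinCorr = exprWithinCorr,
            nTissues = as.integer(nTissues), tissueBias = tissueBias,
            ppiWithinDensity = ppiWithinDensity,
            ppiBetweenDensity = ppiBetweenDensity,
            phyloSpecies = as.integer(phyloSpecies),
            phyloWithinCorr = phyloWithinCorr,
            goFidelity = goFidelity, goPerGeneMean = goPerGeneMean)
  rates <- p[c("multiParentRate", "moduleFidelity",
               "pleiotropyNoiseRate", "exprWithinCorr", "tissueBias",
               "ppiWithinDensity", "ppiBetweenDensity",
               "phyloWithinCorr", "goFidelity")]
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop("all rates and probabilities must lie in [0, 1]")
  if (p$nModules > p$rootBranching)
    stop("infeasible config: more modules (", p$nModules,
         ") than level-1 subtrees (", p$rootBranching, ")")
  new("SyntheticConfig", params = p)
}

# Build a synthetic rooted DAG: `rootBranching` level-1 subtrees, each
# a `branching`-ary tree down to `depth`; a fraction of deeper terms
# gains a second parent at the same upper level (levels unchanged).
synthOntology <- function(prefix, depth, rootBranching, branching,
                          multiParentRate) {
  ids <- sprintf("%s:%07d", prefix, 1L)
  names <- "root"
  parents <- list(character(0))
  level <- 0L
  subtree <- NA_integer_
  prevIdx <- 1L  # indices of previous level's terms
  counter <- 1L
  for (lev in seq_len(depth)) {
    nKids <- if (lev == 1L) rootBranching else branching
    newIdx <- integer(0)
    for (pi in prevIdx) {
      for (kk in seq_len(nKids)) {
        counter <- counter + 1L
        ids[counter] <- sprintf("%s:%07d", prefix, counter)
        names[counter] <- sprintf("synthetic term L%d #%d", lev, counter)
        parents[[counter]] <- ids[pi]
        level[counter] <- lev
        subtree[counter] <- if (lev == 1L) length(newIdx) + 1L
                            else subtree[pi]
        newIdx <- c(newIdx, counter)
      }
    }
    # occasional extra parent drawn from the same upper level
    if (lev >= 2L && multiParentRate > 0) {
      extra <- newIdx[stats::runif(length(newIdx)) < multiParentRate]
      for (ei in extra) {
        cand <- setdiff(prevIdx, match(parents[[ei]], ids))
        if (length(cand))
          parents[[ei]] <- c(parents[[ei]],
                             ids[cand[sample.int(length(cand), 1L)]])
      }
    }
    prevIdx <- newIdx
  }
  names(parents) <- ids
  list(ids = ids, names = stats::setNames(names, ids),
       parents = parents, level = stats::setNames(level, ids),
       subtree = stats::setNames(subtree, ids))
}

writeOBO <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in ont$ids) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", ont$names[id]), con)
    for (p in ont$parents[[id]])
      writeLines(paste0("is_a: ", p, " ! ", ont$names[p]), con)
    writeLines("", con)
  }
  invisible(path)
}

# Draw one annotation term for a gene of module `mod`: stay inside the
# module subtree with probability `fidelity`, otherwise land uniformly
# in another subtree. Term level is drawn from `levelWeights`.
drawTerms <- function(n, ont, mod, fidelity, levelWeights) {
  lv <- sample(seq_along(levelWeights), n, replace = TRUE,
               prob = levelWeights)
  inMod <- stats::runif(n) < fidelity
  vapply(seq_len(n), function(i) {
    pool <- if (inMod[i])
      ont$ids[ont$level == lv[i] & ont$subtree == mod]
    else
      ont$ids[ont$level == lv[i] & ont$subtree != mod &
              !is.na(ont$subtree)]
    pool[sample.int(length(pool), 1L)]
  }, "")
}

# Annotation-level profile peaking mid-ontology (mimics the usage peak
# curated annotation shows around level 5 of a depth-8+ ontology).
annotationLevelWeights <- function(depth, peak = min(5L, depth)) {
  w <- stats::dnorm(seq_len(depth), mean = peak, sd = 1.3)
  w[1] <- 0  # level-1 terms are groups, not annotations
  w / sum(w)
}

#' Generate a synthetic data bundle with planted structure
#'
#' Writes every input the pipeline ingests (ontology OBO, annotation
#' TSV, expression TSV, tissue TSV, PPI TSV, phylogenetic-profile TSV,
#' per-branch GO OBO + annotation TSVs, planted module labels TSV and a
#' manifest JSON with config and file digests) and returns the same
#' data as in-memory objects. Output is byte-identical for identical
#' configs.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir output directory (created if missing).
#' @return invisible list with the in-memory objects (\code{dag},
#'   \code{annotations}, \code{expression}, \code{tissue}, \code{ppi},
#'   \code{phylo}, \code{goDags}, \code{goAnnotations}, \code{modules})
#'   and the \code{paths} of the written files.
#' @export
generateBundle <- function(config, dir = tempfile("bundle")) {
  stopifnot(is(config, "SyntheticConfig"))
  p <- config@params
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(p$seed)
  genes <- sprintf("G%04d", seq_len(p$nGenes))
  modules <- stats::setNames(
    rep(seq_len(p$nModules), length.out = p$nGenes), genes)
  ont <- synthOntology("SP", p$ontologyDepth, p$rootBranching,
                       p$branching, p$multiParentRate)
  lw <- annotationLevelWeights(p$ontologyDepth)
  gene <- character(0); term <- character(0)
  for (g in genes) {
    nAnn <- max(2L, stats::rpois(1L, p$perGeneMean))
    tt <- drawTerms(nAnn, ont, modules[g], p$moduleFidelity, lw)
    nNoise <- stats::rbinom(1L, nAnn, p$pleiotropyNoiseRate)
    if (nNoise > 0) {
      pool <- ont$ids[ont$level >= 2L]
      tt <- c(tt, pool[sample.int(length(pool), nNoise, replace = TRUE)])
    }
    gene <- c(gene, rep(g, length(tt)))
    term <- c(term, tt)
  }
  annotations <- annotationSet(gene, term, source = "synthetic")
  # expression: shared module factor + independent noise
  rho <- p$exprWithinCorr
  fac <- matrix(stats::rnorm(p$nModules * p$exprSamples),
                p$nModules, p$exprSamples)
  expr <- sqrt(rho) * fac[modules[genes], , drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(p$nGenes * p$exprSamples),
                           p$nGenes, p$exprSamples)
  dimnames(expr) <- list(genes, sprintf("S%03d", seq_len(p$exprSamples)))
  # binary tissue matrix: module-preferred tissues
  tisMod <- rep(seq_len(p$nModules), length.out = p$nTissues)
  tisP <- matrix(0.1, p$nGenes, p$nTissues)
  for (m in seq_len(p$nModules))
    tisP[modules[genes] == m, tisMod == m] <- p$tissueBias
  tissue <- matrix(stats::rbinom(length(tisP), 1L, as.vector(tisP)),
                   p$nGenes, p$nTissues,
                   dimnames = list(genes, sprintf("T%03d",
                                                  seq_len(p$nTissues))))
  # PPI: two-density blocks; evidence mostly physical, some rejected
  ppi <- synthPPI(genes, modules, p$ppiWithinDensity,
                  p$ppiBetweenDensity)
  # phylogenetic profiles: module base copy-number profile + noise
  base <- matrix(stats::rpois(p$nModules * p$phyloSpecies, 1.5),
                 p$nModules, p$phyloSpecies)
  keep <- matrix(stats::runif(p$nGenes * p$phyloSpecies) <
                   p$phyloWithinCorr, p$nGenes, p$phyloSpecies)
  noise <- matrix(stats::rpois(p$nGenes * p$phyloSpecies, 1.5),
                  p$nGenes, p$phyloSpecies)
  phylo <- ifelse(keep, base[modules[genes], , drop = FALSE], noise)
  dimnames(phylo) <- list(genes,
                          sprintf("sp%03d", seq_len(p$phyloSpecies)))
  # GO: three branches with their own small DAGs and coherent annotation
  goSpec <- list(BP = c(depth = 6L, peak = 5L),
                 CC = c(depth = 6L, peak = 5L),
                 MF = c(depth = 3L, peak = 2L))
  goOnts <- list(); goAnn <- list()
  for (br in names(goSpec)) {
    o <- synthOntology(paste0("GO", br), goSpec[[br]]["depth"],
                       p$rootBranching, p$branching, 0)
    glw <- annotationLevelWeights(goSpec[[br]]["depth"],
                                  goSpec[[br]]["peak"])
    gg <- character(0); tt <- character(0)
    for (g in genes) {
      nAnn <- max(1L, stats::rpois(1L, p$goPerGeneMean))
      tt <- c(tt, drawTerms(nAnn, o, modules[g], p$goFidelity, glw))
      gg <- c(gg, rep(g, nAnn))
    }
    goOnts[[br]] <- o
    goAnn[[br]] <- annotationSet(gg, tt, source = "synthetic")
  }
  paths <- writeBundleFiles(dir, ont, annotations, expr, tissue, ppi,
                            phylo, goOnts, goAnn, modules, p)
  dag <- computeLevels(parseOBO(paths$ontology))
  goDags <- lapply(names(goOnts), function(br)
    computeLevels(parseOBO(paths[[paste0("go_", br)]])))
  names(goDags) <- names(goOnts)
  invisible(list(config = config, dir = dir, paths = paths, dag = dag,
                 annotations = annotations, expression = expr,
                 tissue = tissue, ppi = ppi, phylo = phylo,
                 goDags = goDags, goAnnotations = goAnn,
                 modules = modules))
}

synthPPI <- function(genes, modules, withinDensity, betweenDensity) {
  n <- length(genes)
  idx <- utils::combn(n, 2L)
  same <- modules[genes[idx[1, ]]] == modules[genes[idx[2, ]]]
  pEdge <- ifelse(same, withinDensity, betweenDensity)
  keep <- stats::runif(ncol(idx)) < pEdge
  a <- genes[idx[1, keep]]; b <- genes[idx[2, keep]]
  ev <- physicalEvidenceTypes()
  evidence <- ev[sample.int(length(ev), length(a), replace = TRUE)]
  # ~8% decoy rows with non-physical evidence, to exercise the filter
  nDecoy <- ceiling(0.08 * length(a))
  if (nDecoy > 0) {
    di <- sample.int(n, nDecoy); dj <- sample.int(n, nDecoy)
    ok <- di != dj
    a <- c(a, genes[di[ok]]); b <- c(b, genes[dj[ok]])
    evidence <- c(evidence,
                  rep(c("Dosage Rescue", "Synthetic Lethality"),
                      length.out = sum(ok)))
  }
  data.frame(a = a, b = b, evidence = evidence, stringsAsFactors = FALSE)
}

writeBundleFiles <- function(dir, ont, annotations, expr, tissue, ppi,
                             phylo, goOnts, goAnn, modules, p) {
  fp <- function(x) file.path(dir, x)
  paths <- list(ontology = fp("ontology.obo"),
                annotations = fp("annotations.tsv"),
                expression = fp("expression.tsv"),
                tissue = fp("tissue.tsv"), ppi = fp("ppi.tsv"),
                phylo = fp("phylo.tsv"), modules = fp("modules.tsv"),
                manifest = fp("manifest.json"))
  writeOBO(ont, paths$ontology)
  writeAnnotations(annotations, paths$annotations)
  writeMatrixTsv(expr, paths$expression, idCol = "gene")
  writeMatrixTsv(tissue, paths$tissue, idCol = "gene")
  writeTsv(ppi, paths$ppi)
  writeMatrixTsv(phylo, paths$phylo, idCol = "gene")
  writeTsv(data.frame(gene = names(modules),
                      module = unname(modules)), paths$modules)
  for (br in names(goOnts)) {
    paths[[paste0("go_", br)]] <- fp(sprintf("go_%s.obo", br))
    paths[[paste0("go_", br, "_annotations")]] <-
      fp(sprintf("go_%s_annotations.tsv", br))
    writeOBO(goOnts[[br]], paths[[paste0("go_", br)]])
    writeAnnotations(goAnn[[br]],
                     paths[[paste0("go_", br, "_annotations")]])
  }
  digests <- tools::md5sum(unlist(paths[names(paths) != "manifest"]))
  manifest <- list(config = p,
                   files = as.list(stats::setNames(unname(digests),
                                                   basename(names(digests)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths
}

#' Generate a structure-free null bundle
#'
#' Same marginal make-up as \code{\link{generateBundle}} but with no
#' planted structure: annotation fidelity at chance level
#' (1 / nModules), no pleiotropy boost, zero expression and
#' phylogenetic within-module correlation, background-level tissue
#' bias, and equal PPI densities (the mean of the configured within and
#' between densities). Used for type-I-error and uniform-p checks.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir output directory.
#' @return as \code{\link{generateBundle}}.
#' @export
nullBundle <- function(config, dir = tempfile("nullbundle")) {
  stopifnot(is(config, "SyntheticConfig"))
  p <- config@params
  meanDensity <- mean(c(p$ppiWithinDensity, p$ppiBetweenDensity))
  pn <- syntheticConfig(
    seed = p$seed, nGenes = p$nGenes, nModules = p$nModules,
    ontologyDepth = p$ontologyDepth, rootBranching = p$rootBranching,
    branching = p$branching, multiParentRate = p$multiParentRate,
    perGeneMean = p$perGeneMean,
    moduleFidelity = 1 / p$nModules, pleiotropyNoiseRate = 0,
    exprSamples = p$exprSamples, exprWithinCorr = 0,
    nTissues = p$nTissues, tissueBias = 0.1,
    ppiWithinDensity = meanDensity, ppiBetweenDensity = meanDensity,
    phyloSpecies = p$phyloSpecies, phyloWithinCorr = 0,
    goFidelity = 1 / p$nModules, goPerGeneMean = p$goPerGeneMean)
  generateBundle(pn, dir)
}
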