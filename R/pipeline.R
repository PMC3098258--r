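# End-to-end orchestration: one configuration drives simulation (or
# file ingestion), biadjacency construction, association networks,
# topology diagnostics, community extraction, enrichment, community
# mapping and phenotype clustering, with deterministic plain-text
# artifacts and a machine-readable manifest.

#' Assemble a pipeline run configuration
#'
#' @param seed master RNG seed; every stochastic stage derives its own
#'   stream from it.
#' @param level ontology analysis level for the biadjacency matrix.
#' @param cutoff edge threshold d_cutoff; NULL to derive it from
#'   \code{cutoffQuantile} of the nonzero d distribution.
#' @param cutoffQuantile upper quantile used when \code{cutoff} is NULL.
#' @param correction FDR correction for the association pipeline.
#' @param nBoot resampling replicates for enrichment controls.
#' @param rewireReps replicates of the degree-preserving rewiring null.
#' @param swapsPerEdge double-edge swaps per edge when rewiring.
#' @param clusterBoot total replicates for phenotype-cluster support.
#' @param goLevels named per-branch GO analysis levels.
#' @param synthetic list of \code{\link{syntheticConfig}} arguments
#'   (seed is filled from \code{seed}) for the simulate stage; NULL to
#'   read pre-existing inputs from \code{inputDir}.
#' @param inputDir directory holding bundle-layout input files when
#'   \code{synthetic} is NULL.
#' @return a named list ("phenonetRunConfig").
#' @export
runConfig <- function(seed, level = 3L, cutoff = NULL,
                      cutoffQuantile = 0.8, correction = "BH",
                      nBoot = 1000L, rewireReps = 1000L,
                      swapsPerEdge = 10L, clusterBoot = 10000L,
                      goLevels = c(BP = 5L, CC = 5L, MF = 2L),
                      synthetic = list(), inputDir = NULL) {
  if (missing(seed)) stop("config error: seed is mandatory")
  cfg <- list(seed = as.integer(seed), level = as.integer(level),
              cutoff = cutoff, cutoffQuantile = cutoffQuantile,
              correction = correction, nBoot = as.integer(nBoot),
              rewireReps = as.integer(rewireReps),
              swapsPerEdge = as.integer(swapsPerEdge),
              clusterBoot = as.integer(clusterBoot),
              goLevels = goLevels, synthetic = synthetic,
              inputDir = inputDir)
  class(cfg) <- "phenonetRunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{runConfig}}.
#'
#' @param path YAML file path.
#' @return a run configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config error: seed is mandatory")
  args <- y[intersect(names(y), names(formals(runConfig)))]
  if (!is.null(args$goLevels)) args$goLevels <- unlist(args$goLevels)
  do.call(runConfig, args)
}

pipelineStages <- function() {
  c("simulate", "build-network", "topology", "communities", "enrich",
    "map-communities", "cluster-phenotypes")
}

logStage <- function(stage, ...) {
  message(sprintf("[phenonet] %s %s: %s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the gene-phenotype network pipeline
#'
#' Chains the analysis stages on one configuration, writing
#' deterministic plain-text artifacts (TSV, OBO, Newick, JSON) under
#' \code{outDir}. Identical configurations produce byte-identical
#' artifacts. Requested stages that depend on earlier ones trigger the
#' prerequisite computations; only the requested stages' artifacts are
#' (re)written.
#'
#' @param config from \code{\link{runConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param outDir output directory.
#' @param stages character vector of stages (see
#'   \code{\link{pipelineStages}}) or "all".
#' @return invisible list of computed objects and artifact paths.
#' @export
runPipeline <- function(config, outDir, stages = "all") {
  stopifnot(inherits(config, "phenonetRunConfig"))
  if (identical(stages, "all")) stages <- pipelineStages()
  bad <- setdiff(stages, pipelineStages())
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  t0 <- proc.time()[3]

  # -- inputs: simulate or ingest -------------------------------------
  if (!is.null(config$synthetic)) {
    sc <- do.call(syntheticConfig,
                  c(list(seed = config$seed), config$synthetic))
    bundleDir <- file.path(outDir, "bundle")
    logStage("simulate", "generating synthetic bundle in ", bundleDir)
    bundle <- generateBundle(sc, bundleDir)
    art$bundle <- bundle$paths
  } else {
    if (is.null(config$inputDir))
      stop("data error: no synthetic config and no inputDir; ",
           "run the simulate stage or point inputDir at a bundle")
    bundle <- readBundleDir(config$inputDir)
  }
  dag <- bundle$dag
  ann <- filterExcluded(bundle$annotations, excludedTermIds(dag))
  dag <- annotateGranularity(dag, ann)

  # -- biadjacency + association networks -----------------------------
  L <- config$level
  logStage("build-network", "biadjacency at level ", L)
  B <- buildBiadjacency(ann, dag, L)
  B1 <- buildBiadjacency(ann, dag, 1L)
  A <- associationMatrix(B, correction = config$correction)
  cutoff <- if (!is.null(config$cutoff)) config$cutoff
            else suggestCutoff(A, config$cutoffQuantile)
  net <- buildNetwork(A, cutoff)
  Ap <- associationMatrix(t(B), correction = config$correction)
  cutoffP <- if (!is.null(config$cutoff)) config$cutoff
             else suggestCutoff(Ap, config$cutoffQuantile)
  netP <- buildNetwork(Ap, cutoffP)
  logStage("build-network",
           sprintf("gene net %d nodes / %d edges (d >= %.4g); %s",
                   length(nodeIds(net)), nrow(edges(net)), cutoff,
                   sprintf("phenotype net %d nodes / %d edges",
                           length(nodeIds(netP)), nrow(edges(netP)))))
  if ("build-network" %in% stages) {
    exportBiadjacency(B, file.path(outDir, "biadjacency.tsv"))
    writeMatrixTsv(values(A), file.path(outDir, "association_gene.tsv"))
    exportNetwork(net, file.path(outDir, "network_gene.tsv"))
    exportNetwork(netP, file.path(outDir, "network_phenotype.tsv"))
    exportNetwork(net, file.path(outDir, "network_gene.graphml"),
                  format = "graphml")
  }

  # -- communities (needed by several later stages) -------------------
  part <- newmanSpectral(net)
  partP <- newmanSpectral(netP)
  logStage("communities",
           sprintf("gene: %d communities, Q = %.3f; phenotype: %d, Q = %.3f",
                   length(unique(communityLabels(part))), modularityQ(part),
                   length(unique(communityLabels(partP))),
                   modularityQ(partP)))
  if ("communities" %in% stages) {
    writePartition(part, file.path(outDir, "partition_gene.tsv"))
    writePartition(partP, file.path(outDir, "partition_phenotype.tsv"))
  }

  # -- topology -------------------------------------------------------
  rew <- NULL
  if ("topology" %in% stages) {
    prof <- degreeProfile(net)
    logStage("topology", sprintf("gamma_hat = %.3f (R2 = %.3f)",
                                 prof@gammaHat, prof@fitR2))
    exportDegreeProfile(prof, file.path(outDir, "degree_profile_gene.tsv"))
    rew <- rewireNull(net, nReps = config$rewireReps,
                      swapsPerEdge = config$swapsPerEdge,
                      seed = deriveSeed(config$seed, "rewire"))
    writeTsv(data.frame(replicate = seq_len(rew@nReps),
                        meanC = rew@nullC, Q = rew@nullQ),
             file.path(outDir, "rewire_null.tsv"))
    writeTsv(data.frame(stat = c("meanC", "Q"),
                        observed = c(rew@observedC, rew@observedQ),
                        p = c(rew@pC, rew@pQ)),
             file.path(outDir, "rewire_summary.tsv"))
  }

  # -- enrichment -----------------------------------------------------
  enr <- list()
  if ("enrich" %in% stages) {
    nb <- config$nBoot
    enr$expr_corr <- communityEnrichment(
      part, pairwiseCorrelation(bundle$expression), "expr_corr",
      nBoot = nb, seed = deriveSeed(config$seed, "expr"))
    enr$tissue_corr <- communityEnrichment(
      part, pairwiseCorrelation(bundle$tissue), "tissue_corr",
      nBoot = nb, seed = deriveSeed(config$seed, "tissue"))
    enr$phylo_corr <- communityEnrichment(
      part, pairwiseCorrelation(bundle$phylo), "phylo_corr",
      nBoot = nb, seed = deriveSeed(config$seed, "phylo"))
    ppiPairs <- bundle$ppi[bundle$ppi$evidence %in%
                             physicalEvidenceTypes(), c("a", "b")]
    enr$ppi_count <- ppiCountEnrichment(
      part, ppiPairs, nBoot = nb,
      seed = deriveSeed(config$seed, "ppi"))
    go <- goSimilarityD(part, bundle$goAnnotations, bundle$goDags,
                        levels = config$goLevels, nBoot = nb,
                        seed = deriveSeed(config$seed, "go"))
    for (br in names(go)) enr[[paste0("go_d_", br)]] <- go[[br]]
    ptab <- data.frame(
      metric = names(enr),
      p = vapply(enr, function(e) e@pValue, 0))
    writeTsv(ptab, file.path(outDir, "enrichment.tsv"))
    for (e in enr) logStage("enrich", sprintf("%s p = %.3g",
                                              e@metric, e@pValue))
    hubs <- hubNodes(net)
    goPooled <- do.call(mergeAnnotations, unname(bundle$goAnnotations))
    hubTab <- tryCatch(
      hubGOFisher(hubs, nodeIds(net), goPooled),
      error = function(e) NULL)
    if (!is.null(hubTab))
      writeTsv(hubTab, file.path(outDir, "hub_go_enrichment.tsv"))
    ct <- level1SharingChisq(part, B1)
    writeTsv(data.frame(stat = c("chiSq", "dof", "p", "fracSameWithin",
                                 "fracSameOverall"),
                        value = c(ct@chiSq, ct@dof, ct@p,
                                  ct@fracSameWithin, ct@fracSameOverall)),
             file.path(outDir, "level1_sharing.tsv"))
  }

  # -- community-to-group mapping -------------------------------------
  if ("map-communities" %in% stages) {
    cg <- communityGroupMatrix(part, B1)
    writeOverlapMatrix(cg, file.path(outDir, "community_group.tsv"))
    writeTsv(data.frame(gene = rownames(values(B1)),
                        group = unname(highestScoringLevel1(B1))),
             file.path(outDir, "gene_level1_group.tsv"))
  }

  # -- phenotype clustering -------------------------------------------
  if ("cluster-phenotypes" %in% stages) {
    dendro <- bootstrapSupport(B1, nBoot = config$clusterBoot,
                               seed = deriveSeed(config$seed, "dendro"))
    exportDendrogram(dendro, file.path(outDir, "phenotype_clusters.nwk"))
    exportDendrogram(dendro, file.path(outDir, "phenotype_clusters.tsv"),
                     format = "tsv")
    logStage("cluster-phenotypes",
             sprintf("%d clusters with AU >= 0.95",
                     sum(dendro@au >= 0.95, na.rm = TRUE)))
  }

  # -- manifest -------------------------------------------------------
  arts <- setdiff(list.files(outDir, recursive = TRUE,
                             full.names = TRUE),
                  file.path(outDir, "manifest.json"))
  digests <- tools::md5sum(sort(arts))
  manifest <- list(
    config = config[setdiff(names(config), "goLevels")],
    goLevels = as.list(config$goLevels),
    stages = stages,
    artifacts = as.list(stats::setNames(
      unname(digests),
      sub(paste0("^", outDir, "/?"), "", names(digests)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logStage("done", sprintf("%.1f s elapsed", proc.time()[3] - t0))
  invisible(list(bundle = bundle, dag = dag, annotations = ann,
                 biadjacency = B, biadjacencyL1 = B1, association = A,
                 network = net, networkPhenotype = netP,
                 partition = part, partitionPhenotype = partP,
                 rewiring = rew, enrichment = enr, outDir = outDir))
}

# Read a bundle-layout directory written by generateBundle().
readBundleDir <- function(dir) {
  need <- c(ontology = "ontology.obo", annotations = "annotations.tsv")
  for (nm in names(need)) {
    if (!file.exists(file.path(dir, need[nm])))
      stop("data error: missing ", need[nm], " in ", dir,
           "; produce it with the simulate stage (generateBundle)")
  }
  dag <- computeLevels(parseOBO(file.path(dir, "ontology.obo")))
  ann <- readAnnotations(file.path(dir, "annotations.tsv"),
                         source = "synthetic", header = TRUE)
  opt <- function(f, reader) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  goDags <- list(); goAnn <- list()
  for (br in c("BP", "CC", "MF")) {
    oboP <- file.path(dir, sprintf("go_%s.obo", br))
    annP <- file.path(dir, sprintf("go_%s_annotations.tsv", br))
    if (file.exists(oboP) && file.exists(annP)) {
      goDags[[br]] <- computeLevels(parseOBO(oboP))
      goAnn[[br]] <- readAnnotations(annP, source = "synthetic",
                                     header = TRUE)
    }
  }
  list(dag = dag, annotations = ann,
       expression = opt("expression.tsv", readMatrixTsv),
       tissue = opt("tissue.tsv", readMatrixTsv),
       ppi = opt("ppi.tsv", function(p) {
         df <- readTsv(p)
         names(df)[1:3] <- c("a", "b", "evidence")
         df
       }),
       phylo = opt("phylo.tsv", readMatrixTsv),
       goDags = goDags, goAnnotations = goAnn,
       modules = opt("modules.tsv", function(p) {
         df <- readTsv(p)
         stats::setNames(as.integer(df[[2]]), df[[1]])
       }))
}
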