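# Shared fixtures: tiny ontologies written as OBO text, hand-sized
# annotation sets, network constructors, and memoized synthetic bundles
# reused across test files.

oboLines <- function(...) {
  c("format-version: 1.2", "", ...)
}

oboTerm <- function(id, name = id, isa = character(0),
                    obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("is_a: ", isa),
    if (obsolete) "is_obsolete: true", "")
}

writeOboFile <- function(...) {
  f <- tempfile(fileext = ".obo")
  writeLines(oboLines(...), f)
  f
}

# root -> A -> B chain
chainDag <- function() {
  f <- writeOboFile(oboTerm("T:0", "root"),
                    oboTerm("T:A", "a", "T:0"),
                    oboTerm("T:B", "b", "T:A"))
  computeLevels(parseOBO(f))
}

# diamond: root -> A, root -> B, A -> C, B -> C
diamondDag <- function() {
  f <- writeOboFile(oboTerm("T:0", "root"),
                    oboTerm("T:A", "a", "T:0"),
                    oboTerm("T:B", "b", "T:0"),
                    oboTerm("T:C", "c", c("T:A", "T:B")))
  computeLevels(parseOBO(f))
}

makeAnnotations <- function(gene, term) {
  phenonet:::annotationSet(gene, term, source = "synthetic")
}

# NetworkEdgeList from an undirected edge data.frame (weight 1).
makeNet <- function(from, to, weight = 1) {
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  e <- data.frame(from = from, to = to,
                  weight = rep_len(weight, length(from)),
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  new("NetworkEdgeList", edges = e,
      nodes = sort(unique(c(e$from, e$to))), dCutoff = 0,
      kind = "gene")
}

igraphToNet <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  makeNet(as.character(e$from), as.character(e$to))
}

# WeightedBiadjacency wrapper around a bare matrix (for clustering and
# mapping tests that only use the aggregated values).
makeBiadjacency <- function(m, level = 1L, kind = "gene") {
  new("WeightedBiadjacency", values = m, level = as.integer(level),
      kind = kind,
      triples = data.frame(object = character(0), column = character(0),
                           term = character(0), weight = numeric(0),
                           stringsAsFactors = FALSE))
}

# Memoized bundles shared across test files (built once per run).
.fixtureCache <- new.env(parent = emptyenv())

cachedBundle <- function(name, maker) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- maker()
  .fixtureCache[[name]]
}

smallBundle <- function() {
  cachedBundle("small", function() {
    cfg <- syntheticConfig(seed = 42, nGenes = 60, nModules = 3,
                           exprSamples = 30)
    generateBundle(cfg, file.path(tempdir(), "phenonet-small-bundle"))
  })
}

# The planted study-condition bundle: 300 genes, 5 modules,
# fidelity 0.9, noise 0.05 (generator defaults), fixed seed.
plantedBundle <- function() {
  cachedBundle("planted", function() {
    cfg <- syntheticConfig(seed = 20110519)
    generateBundle(cfg, file.path(tempdir(), "phenonet-planted-bundle"))
  })
}

plantedAnalysis <- function() {
  cachedBundle("plantedAnalysis", function() {
    b <- plantedBundle()
    dag <- annotateGranularity(b$dag, b$annotations)
    B <- buildBiadjacency(b$annotations, dag, 3L)
    A <- associationMatrix(B)
    net <- buildNetwork(A, suggestCutoff(A, 0.8))
    part <- newmanSpectral(net)
    list(bundle = b, dag = dag, B = B,
         B1 = buildBiadjacency(b$annotations, dag, 1L),
         A = A, net = net, part = part)
  })
}

nullAnalysisBundle <- function() {
  cachedBundle("null", function() {
    cfg <- syntheticConfig(seed = 20110519)
    nullBundle(cfg, file.path(tempdir(), "phenonet-null-bundle"))
  })
}
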