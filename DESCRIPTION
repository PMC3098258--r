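Package: phenonet
Title: Gene-Phenotype Association Networks from Ontology Annotations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted gene-by-phenotype biadjacency matrices from
    ontology-annotated gene-phenotype associations (e.g. Mammalian
    Phenotype annotations of mouse knockouts), derives gene-gene and
    phenotype-phenotype association networks from a Wilcoxon-based,
    FDR-corrected pairwise similarity score, extracts communities with
    Newman's spectral modularity method, characterises network topology
    against degree-preserving rewiring nulls, tests communities for
    coexpression, tissue-expression, protein-protein interaction, Gene
    Ontology similarity and phylogenetic-profile enrichment against
    resampled controls, maps communities to high-level phenotype groups
    and across networks via hypergeometric overlap probabilities, and
    clusters high-level phenotypes with multiscale-bootstrap (AU) support.
    A synthetic-data generator with planted module structure makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Clustering, GeneExpression, Software
RoxygenNote: 7.3.3
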