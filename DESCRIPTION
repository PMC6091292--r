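Package: pathnet
Title: Pathway Network Analysis for Case-Control Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes disease-associated biological pathways from a
    case-control gene expression study by combining protein-protein
    interaction filtering of differentially expressed genes, pathway
    activity scoring, mutual information with the phenotype, a
    GO-semantic-similarity pathway-pathway network (Wang measure with
    best-match-average gene combination), a GeneRank random walk seeded
    with mutual information, and hypergeometric enrichment significance.
    Includes a classification-based evaluation (linear SVM, stratified
    repeated cross-validation AUC) against a t-test gene-ranking
    baseline, a synthetic data generator with planted disease pathways,
    and readers/writers for the standard formats involved (expression
    TSV, GMT, edge-list TSV, OBO, GAF).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
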