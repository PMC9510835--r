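Package: coexmark
Title: Weighted Co-Expression Modules, Consensus Hub Ranking and SVM-RFE
    Biomarker Discovery for Whole-Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a whole-blood mRNA biomarker
    discovery workflow for ankylosing spondylitis: weighted gene
    co-expression network analysis (soft-threshold selection by scale-free
    topology fit, topological overlap, static-cut module detection with
    eigengene merging, module-trait selection), empirical-Bayes moderated-t
    differential expression with Benjamini-Hochberg control, pre-ranked
    permutation gene-set enrichment, a twelve-measure consensus hub-gene
    ranking over protein-interaction networks, and SVM recursive feature
    elimination with a cross-validated error curve. A synthetic-data
    generator plants known co-expression modules, discriminative genes and
    network hubs so every stage can be scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
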