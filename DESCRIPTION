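Package: lelpipe
Title: Differential Expression Pipeline for the Loss-of-Epithelial-Layer
    Organ Culture Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired two-condition expression
    microarray studies of the loss-of-epithelial-layer (LEL) intestinal
    organ culture model. Provides variance-stabilizing normalization via
    per-array affine calibration and a generalized-log transform, paired
    differential expression with empirical-Bayes variance moderation and
    Benjamini-Hochberg adjustment, over-representation analysis of gene
    ontology terms with the hypergeometric test conditional on the
    ontology structure, a permutation test for the significance of
    cross-study gene-list overlap, heatmap preparation (gene-wise
    z-transform, complete-linkage hierarchical clustering), and
    housekeeping-gene normalization of qRT-PCR transcript counts. A
    synthetic-data generator with known ground truth makes every stage
    testable without access to the original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
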