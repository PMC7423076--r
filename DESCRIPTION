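Package: stableRG
Title: Reference Gene Discovery and Stability Analysis for qPCR Normalization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating stable reference genes for
    relative qPCR quantification of biomarkers in haematological malignancies.
    Implements a genome-wide expression-stability screen over multiple RNA-seq
    FPKM datasets (dispersion statistics, PAM clustering with silhouette model
    selection, Gene Ontology stop-word and cytogenetic translocation-proximity
    filters, composite quartile ranking), qPCR quantification math
    (amplification factors, NTC-anchored delta-Cq, relative expression,
    normalization factors, relative quantification), four reference-gene
    stability algorithms (geNorm, NormFinder, BestKeeper, comparative delta-Ct)
    with consensus and comprehensive geometric-mean ranks, and synthetic data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    cluster,
    matrixStats,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
biocViews: GeneExpression, Normalization, qPCR, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
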