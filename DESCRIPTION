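Package: gcmultiomics
Title: Multi-Omic Analysis of Growth Cone Development and Optic Nerve
    Regeneration Lipidomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for integrated proteomic and lipidomic
    analysis of neuronal growth cones across developmental stages and of
    lipid remodelling during induced optic nerve regeneration. Provides a
    synthetic multi-omic data generator with planted, recoverable effects;
    normalization, coefficient-of-variation quality control and lipid
    shorthand-name parsing; PCA, ANOVA-simultaneous component analysis,
    PLS stage regression with variable-importance-in-projection scores,
    Ward clustering and k-means early/late partitioning; volcano and
    linear stage-trend statistics with Benjamini-Hochberg correction;
    Fisher exact term enrichment; protein-lipid correlation networks with
    dual-requirement protein-protein edge filtering and Fisher
    r-to-Z-to-r correlation combination; empirical-Bayes batch correction
    and ROC-based lipid biomarker ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    pROC,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
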