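Package: qtlmediate
Title: Colocalization and Mediated Heritability of Chromatin Accessibility
    and Expression QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how chromatin
    accessibility QTLs (caQTLs) and expression QTLs (eQTLs) mediate complex
    disease heritability. Provides a synthetic-data generator with known
    causal architecture (LD-structured genotypes, peak-level causal variants,
    distance-decaying peak-to-gene wiring, context-specific regulation, and
    GWAS summary statistics drawn from the multivariate normal law), cis-QTL
    mapping with TMM/CPM filtering, inverse-normal transformation and
    parallel-analysis covariate selection, approximate-Bayes-factor
    colocalization over five causal configurations, inverse-variance-weighted
    fixed-effects meta-analysis, LD-score and mediation-score regression for
    stratified and QTL-mediated heritability with union/intersection
    decomposition, Haseman-Elston cis-heritability estimation, and
    peak-to-TSS-distance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
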