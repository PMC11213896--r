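Package: t21subtypes
Title: Molecular Subtype Discovery for Trisomy 21 Multiomics Cohorts
Version: 0.1.0
Authors@R:
    person("Trisomy Multiomics", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterizing molecular subtypes of
    trisomy 21 (Down syndrome) from whole-blood multiomics data. Implements
    quantification of variegated chromosome 21 (HSA21) gene overexpression,
    Spearman co-expression clustering of HSA21 genes into two gene clusters,
    resampling-based consensus clustering of individuals with delta-area
    k-selection, polygenic and cytokine composite z-score indices, a generic
    per-feature log-linear differential abundance engine with
    Benjamini-Hochberg control, preranked gene set enrichment, longitudinal
    stability analysis, and ratio-based clinical classifiers with percentile
    cutoffs. Includes a synthetic multiomics cohort generator that plants the
    assumed statistical structure (chromosome dosage, anti-correlated gene
    clusters, latent subtypes, inflammatory panels, compositional immune-cell
    shifts) so that the full pipeline is testable end to end without access
    to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
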