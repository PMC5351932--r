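Package: crossmeth
Title: Cross-Brain-Region Methylome Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for array-based DNA methylation studies
    across multiple brain regions and cohorts: beta-level quality control and
    within-probe-type quantile normalization, probe-wise epigenome-wide
    association (EWAS) against diagnosis or polygenic risk score,
    inverse-variance fixed-effects meta-analysis across cohorts, a
    cross-region mixed model, detection of differentially methylated regions
    by autocorrelation-corrected Stouffer-Liptak combination with Sidak
    correction, permutation-based family-wise error thresholds, neuronal
    proportion and DNA-methylation-age covariates, genotype QC, LD pruning,
    polygenic risk scoring, methylation QTL scanning and GWAS-region
    enrichment. Includes a synthetic-data generator that emulates a
    two-cohort, four-region post-mortem brain study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    lme4,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    knitr
Config/testthat/edition: 3
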