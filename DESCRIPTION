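Package: sipiScan
Title: SNP-SNP Interaction Pattern Scanning for Case-Control Association Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pairwise SNP-SNP interaction analysis for binary clinical
    outcomes using a catalogue of 45 inheritance-mode interaction patterns
    with Bayesian information criterion model selection, single-variant
    association under additive, dominant and recessive codings,
    Bonferroni multiplicity thresholds, and bootstrap internal validation
    with the 3pRule significance criterion. Includes a Hardy-Weinberg
    synthetic cohort generator with configurable linkage disequilibrium,
    covariate distributions and interaction effect sizes emulating
    case-only prostate cancer aggressiveness strata, plus reporting
    utilities (single-variant tables, pair tables, genotype-combination
    prevalence grids, cohort summaries) and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    GenomeInfoDb,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: SNP, GeneticVariability, StatisticalMethod, Genetics
RoxygenNote: 7.3.3
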