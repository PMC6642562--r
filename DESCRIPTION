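Package: fcomix
Title: Fetal Cell Origin Fraction Estimation from DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the fraction of cells of fetal origin (FCO) in bulk
    tissue samples from Illumina 450K DNA methylation beta values by
    constrained least-squares projection onto a fetal/adult reference CpG
    library. Provides readers for beta-value matrices (plain, TCGA
    level-3-like, and GEO series-matrix dialects), library alignment and
    present-probe quality control, a grid-search oracle and leave-k-probe-out
    stability analysis for the mixture estimates, tumor versus nontumor
    comparison by Wilcoxon rank-sum test, covariate-adjusted linear models and
    a randomization-based empirical-null test, sensitivity analyses
    (age/purity/leukocyte-infiltration correlations, purity-adjusted models,
    interquartile-range screening, stage trends, per-probe extraction), a
    synthetic cohort simulator with known ground-truth fractions, and an
    end-to-end pipeline with deterministic, seeded outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
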