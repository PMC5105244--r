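Package: csfqtl
Title: Quantitative-Trait GWAS and Genetic Adjustment of CSF Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-variant quantitative-trait association analysis for
    cerebrospinal-fluid protein biomarkers (such as YKL-40), with genotype
    quality control (call rate, Hardy-Weinberg exact test, minor allele
    frequency, duplicate detection, EIGENSTRAT-style principal components),
    additive-model regression with covariates, conditional analysis, genomic
    inflation diagnostics, variance decomposition of the biomarker into
    covariate and top-locus components, genetic residualization via
    studentized residuals, and formal comparison of dependent overlapping
    correlations (Meng Z-test) before and after adjustment.  Includes a
    cohort simulator that reproduces the statistical structure these
    analyses assume, a logistic case/control association stage, and an
    end-to-end reproducible pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
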