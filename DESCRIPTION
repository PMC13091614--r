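Package: snprecall
Title: Post Hoc Machine-Learning Genotype Recalling for SNP Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recalls genotypes on Illumina-style SNP microarray exports from
    per-SNP two-channel summary statistics. GenomeStudio-style final-report
    tables are parsed into a SummarizedExperiment-derived container, passed
    through record-level quality control, engineered into angle-error and
    subtended-arc features, and classified into AA/AB/BB posteriors by
    regularized multinomial logistic regression, gradient-boosted trees, or a
    small neural network, trained with group-wise cross-validation. Calls
    carry Phred-scaled genotype qualities and can be filtered by quality
    threshold, rank-matched GenCall sets, or concordance with the platform
    call, then written as VCF. Evaluation utilities compute call rates,
    accuracy, per-class F1, exact paired sign tests, and KING-robust kinship
    coefficients. A built-in dilution-series simulator generates
    pedigree-structured two-channel data with input-dependent degradation and
    heterozygote dropout so the whole pipeline is testable without array
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
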