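Package: mmimpute
Title: Pedigree-Based Multivariate Mixed-Model Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputation of missing biallelic SNP genotypes in structured
    plant populations using a sliding-window multivariate mixed model on the
    pedigree numerator relationship matrix, with restricted maximum
    likelihood (REML) covariance estimation and empirical-Bayes (BLUP)
    prediction of missing gene content. Includes non-parametric baseline
    imputers (k-nearest neighbours, iterative truncated SVD with
    bi-cross-validation rank selection, modal imputation, and an adapter for
    external tools), gene-content marker-heritability and allele-frequency
    quality filters, post-imputation quality metrics (identity accuracy,
    heterozygosity, repeated markers), intra-class-correlation heritability
    and cross-validated genomic prediction accuracy for comparing imputation
    methods, and a nested-association-mapping (NAM) population simulator
    that provides truth panels for all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
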