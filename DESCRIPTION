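Package: regenphen
Title: Curation and Validation of Historical Seed-Regeneration Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating unbalanced historical phenotypic data collected
    during genebank seed regeneration. Fits the two-way mixed model
    trait = mu + genotype + year + error with year-specific residual variances
    by restricted maximum likelihood (average-information updates with EM
    fallback), flags outliers from MAD-rescaled standardized residuals with a
    Bonferroni-Holm test, computes best linear unbiased estimates (BLUEs) of
    accessions, entry-mean heritability, per-year coefficients of variation and
    year-pair correlations, and runs resampling studies (missing-data bias
    scenarios and split-half precision). A synthetic-data generator with known
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
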