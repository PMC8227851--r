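Package: ec11
Title: Eye-Colour Prediction from SNP Panels with Quantitative PIE-Score Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic eye-colour prediction from small SNP panels.
    Implements the quantitative pixel-index-of-the-eye (PIE) score, its logit
    transform and two-/three-category reporting systems; genotype encoding
    (additive, dominant, carrier and combined codings) for named panels
    (EC11, IrisPlex, rs12913832-only); a resampled multi-model variable
    importance ranking and selection procedure combining LASSO regressions and
    CART trees; leave-one-out cross-validated prediction models under each
    reporting system with mean-squared-error, log-loss and Kullback-Leibler
    prediction errors; threshold-based forensic reporting with sensitivity,
    specificity and likelihood ratios; genotype-space enumeration; and a
    synthetic-cohort generator producing Hardy-Weinberg genotypes at published
    allele frequencies with a configurable genotype-to-phenotype model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
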