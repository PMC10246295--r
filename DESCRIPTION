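Package: rvarch
Title: Rare-Variant Association and Genetic Architecture Analysis with
    External Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of early-onset
    complex disease from case-control exome data with external controls.
    Provides principal-component based ancestry matching of external
    controls to cases, single-variant and nested-mask gene-level rare
    variant burden tests with Firth-penalized logistic regression and
    per-gene effective-number-of-tests correction, gene-set enrichment
    against variant-count and frequency matched backgrounds, liability
    threshold model estimates of variance explained with conditional
    maximum-likelihood winner's-curse correction and shared-control-aware
    cross-study comparison, per-individual rare/common/monogenic
    contribution scores with phenotype regressions, and a seeded synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
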