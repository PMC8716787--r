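Package: ggiboost
Title: Gene-Based Gene-Gene Interaction Testing with Constrained Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects statistical interaction (epistasis) between two genes in
    case-control genotype data. Gradient-boosted tree classifiers are fitted with
    and without a feature-interaction constraint that forbids splits mixing SNPs
    from different genes; the relative increase in cross-validated
    misclassification error caused by the additivity constraint is the test
    statistic, and a label-permutation resampling scheme supplies its null
    distribution and p-value. Includes quality control for genotype matrices
    (missingness, minor allele frequency, Hardy-Weinberg equilibrium in
    controls), a semi-empirical two-locus disease simulator driven by haplotype
    resampling with block linkage disequilibrium, a Monte-Carlo harness for
    type-I error and power, and marker-level interaction mining from tree
    ensembles (per-pair split-gain statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xgboost,
    jsonlite,
    stats,
    utils,
    graphics,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
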