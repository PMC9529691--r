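Package: mrphewas
Title: Mendelian Randomization Phenome-Wide Scans with Genetic Risk Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phenome-wide Mendelian randomization (MR-pheWAS)
    with weighted genetic risk score instruments. Provides weighted
    allele-score construction with orientation canonicalization and
    distance/r-squared instrument pruning, an automated rule-based phenome
    scan that routes each trait to linear, logistic, ordered-logistic or
    multinomial regression with covariate adjustment, rank-based false
    discovery rate and Bonferroni thresholding, one-sample two-stage MR,
    and a two-sample MR estimator suite (inverse-variance weighted,
    MR-Egger with intercept test, weighted median, simple and weighted
    mode) operating on harmonized GWAS summary statistics. A synthetic
    cohort generator with known ground truth supports calibration,
    parameter-recovery and negative-control experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    nnet,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
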