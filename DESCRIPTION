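Package: plsSubtype
Title: Multiclass Molecular Subtype Prediction by Partial Least Squares
    Regression for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits one-versus-rest partial least squares (PLS) regression
    classifiers for breast cancer intrinsic (PAM50) molecular subtypes.
    Latent gene components are extracted by NIPALS from class-specific
    10-gene panels, the number of components is chosen by split-sample
    cross-validation PRESS with van der Voet's randomization test, and
    binary logistic regression on the component scores yields
    cross-validated subtype probabilities with ambiguous and unclassified
    outcomes.  Also provides the nearest-centroid single sample predictor
    (Spearman correlation) used as comparator, weighted Cohen's kappa
    agreement statistics, expectation-maximization imputation of missing
    expression values, IQR-based probeset collapsing, and a synthetic
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
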