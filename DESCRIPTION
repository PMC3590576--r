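Package: fsklr
Title: Beta-Turn Prediction with Fixed-Size Kernel Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue prediction of beta-turns in protein chains using
    fixed-size kernel logistic regression: an RBF-kernel logistic model made
    sparse by restricting the kernel expansion to prototype vectors selected
    with k-means, approximated with the Nystrom low-rank eigen-expansion and
    fitted in the primal by a trust-region Newton method.  Features combine a
    sliding window of logistic-scaled PSSM profiles with indicator, confidence
    and composition blocks from four three-state secondary-structure
    predictors, reduced by information-gain and chi-squared ranking.  Raw
    per-residue probabilities are thresholded and smoothed with ordered
    state-changing rules that enforce the minimum four-residue run length of
    beta-turns.  Includes an exact dual-form kernel logistic regression for
    small problems, confusion-matrix quality measures (MCC, Q-measures,
    specificity), ROC/AUC, chain-level sevenfold cross-validation,
    hyperparameter tuning, a prototype-count search, and a seeded synthetic
    data generator emulating all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
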