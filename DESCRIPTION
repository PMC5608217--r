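Package: frmt
Title: Ensemble Feature Ranking for Proteomic Stage Classification via TOPSIS
Version: 0.1.0
Authors@R: person("FRMT", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Ranks features of a two-class protein-expression matrix by fusing
    ten filter feature-selection criteria (two-sample t-test, Wilcoxon rank
    sum, and eight greedy information-theoretic criteria: MIM, MIFS, mRMR,
    JMI, DISR, CMIM, ICAP, CIFE) with the TOPSIS multi-criteria decision
    procedure. Includes plug-in discrete information-theoretic estimators,
    repeated stratified cross-validation scored by the Matthews correlation
    coefficient and AUC, winning-frequency comparisons across selectors,
    classifiers and feature-subset sizes, and a synthetic RPPA-like data
    generator with planted discriminative features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
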