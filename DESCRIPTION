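Package: smrtriad
Title: Three-Step Summary-Data Mendelian Randomization with HEIDI and
    Colocalization for Blood Causal-Gene Triangulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Summary-statistics causal triangulation for prioritizing
    peripheral-blood causal genes: fixed-effects inverse-variance-weighted
    GWAS meta-analysis, two-sample Mendelian randomization with Steiger
    directionality filtering, the three-step SMR framework
    (expression-to-disease, methylation-to-disease,
    methylation-to-expression) with the HEIDI heterogeneity test, Bayesian
    colocalization via approximate Bayes factors (PP.H0-PP.H4), and
    sign-chain interpretation of methylation-expression-disease effect
    directions. Includes an LD-aware multivariate-normal simulator of
    coupled mQTL/eQTL/GWAS summary statistics with known causal topology
    for calibration and power evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
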