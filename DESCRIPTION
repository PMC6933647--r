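Package: bwsweight
Title: Patient-Centered Composite Endpoint Weights from Best-Worst Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving patient-centered component weights for
    composite clinical endpoints from Best-Worst Scaling (MaxDiff) choice
    experiments. Constructs blocked, balanced choice designs with
    D-efficiency diagnostics; simulates best-worst responses under a known
    mixed-logit truth; estimates outcome utilities with a hierarchical
    Bayesian multinomial logit (Gibbs sampling for the population layer,
    adaptive Metropolis-Hastings for respondent part-worths) alongside a
    pooled maximum-likelihood fit; screens for preference heterogeneity
    across respondent covariates; converts utilities into composite
    component weights via a conditional-logit share formula with subgroup
    adjustment and sensitivity intervals; and compares two-arm trials on a
    multi-component endpoint with unweighted and weighted analyses
    (Fisher's exact test, time-to-first-event and weighted recurrent-event
    Cox models, global-rank Wilcoxon with a Probability Index, and
    random-effects logistic models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    glmmTMB,
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
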