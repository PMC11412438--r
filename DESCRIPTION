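Package: bop2mams
Title: Bayesian Optimal Phase II Designs for Multi-Arm Multi-Stage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of multi-arm multi-stage phase II clinical
    trials with co-primary binary efficacy and toxicity endpoints, generalizing
    the Bayesian Optimal Phase II (BOP2) design. The four joint outcomes per
    patient follow a multinomial distribution with a conjugate Dirichlet prior,
    so the marginal response and toxicity rates have Beta posteriors that drive
    futility and toxicity stopping rules at each interim analysis, against
    fixed reference rates (uncontrolled setting) or a randomized control arm
    (controlled setting, via posterior exceedance probabilities). Provides
    sample-size-dependent decision-threshold families, including one that
    adapts to the number of active arms, grid-search calibration controlling
    the family-wise type I error rate under the global null while maximizing
    power under the least favourable configuration, a trial simulator with
    flexible accrual plans, and estimation of operating characteristics
    (selection rates, early stopping, expected sample size, FWER, power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
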