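Package: referralsim
Title: Counterfactual Surgical Referral Simulation with Wilson-Score
    Facility Quality Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for profiling surgical facility quality from
    encounter-level administrative data and simulating counterfactual
    referral of patients to higher-quality facilities.  Facility serious
    adverse event (SAE) rates are estimated with Wilson score intervals,
    facilities are ranked by interval midpoint into quality quartiles,
    risk-adjusted outcome models with facility fixed effects are fitted on a
    training cohort, and test-cohort patients are counterfactually
    reassigned to higher-quality facilities under proximity or health-system
    constraints.  Paired statistics quantify the predicted change in SAE
    risk, cost, length of stay and readmission.  A synthetic encounter
    generator emulating state inpatient/ambulatory surgery databases makes
    the whole pipeline testable without access to licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
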