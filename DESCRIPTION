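Package: brscore
Title: Benefit-Risk Scoring for Implementing Personalized Prognostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic framework for judging whether a personalized
    prognostic model with limited predictive performance should be turned into
    a clinical tool. Enumerates the 16 possible combinations of a patient's a
    priori treatment intent, the model's binary outcome prediction, actual
    treatment participation and counterfactual benefit status; allocates a
    cohort across these possibilities from stated branching probabilities;
    scores each possibility on a common additive scale for benefit or harm,
    placebo and nocebo effects, and treatment side effects; and condenses the
    population-level result into a single Benefit-Risk Score whose sign
    recommends implementing or refraining. Includes one-way sensitivity
    sweeps, decision-boundary threshold finding, partial (clinician-gatekept)
    implementation scenarios, a pre-implementation checklist report, a
    patient-level microsimulation oracle, and a packaged osteoarthritis
    worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
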