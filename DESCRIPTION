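Package: xenoscale
Title: Translational Tumor Growth Inhibition Modeling from PDX Mice to Virtual Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tumor size dynamics and time-to-progression in treated
    cancer patients starting from tumor-growth-inhibition (TGI) studies in
    patient-derived-xenograft (PDX) mice. Provides population fitting of the
    Simeoni TGI model on control/treated arm means (two-stage maximum
    likelihood with nonparametric bootstrap), allometric scaling of the
    exponential growth rate and drug potency to humans with propagation of
    inter-PDX variability, linear compartmental pharmacokinetic simulation of
    standard gemcitabine and sorafenib regimens, and Monte Carlo virtual
    clinical trials that summarise Kaplan-Meier time-to-progression curves
    and tumor diameter trajectories as medians with 90% prediction intervals.
    A synthetic PDX panel generator makes the whole pipeline testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    expm,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
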