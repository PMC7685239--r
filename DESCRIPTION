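Package: pedpk
Title: Population Pharmacokinetics of Solifenacin in Pediatric Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-pharmacokinetic analysis toolkit for solifenacin in
    pediatric patients with overactive bladder or neurogenic detrusor
    overactivity. Provides closed-form one- and two-compartment oral
    absorption models with lag time, a covariate model with fat-free-mass
    allometry, alpha-1-acid-glycoprotein power terms and CYP3A4 ontogeny,
    a clinical-trial simulator with weight-adjusted pediatric-equivalent
    dose titration, sparse sampling windows and assay-limit censoring,
    Laplace-approximation nonlinear mixed-effects estimation with
    empirical-Bayes individual estimates, and dose-normalized exposure
    summaries with classification against an adult reference interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
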