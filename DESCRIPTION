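Package: meropta
Title: Meropenem Population Pharmacokinetics and Probability of Target
    Attainment Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment intravenous-infusion kinetics for meropenem with
    the published population model for healthy adults (serum-creatinine
    covariate on clearance, shared-eta interindividual variability), Monte
    Carlo probability-of-target-attainment (PTA) simulation against fT>MIC
    pharmacodynamic targets and the EUCAST Pseudomonas aeruginosa MIC
    distribution, noncompartmental analysis (linear-up/log-down trapezoid,
    terminal-slope regression), renal-function equations (Cockcroft-Gault,
    MDRD, CKD-EPI), a synthetic-trial generator emitting NONMEM-style
    datasets, and a per-subject parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
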