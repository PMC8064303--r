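Package: pippk
Title: Population Pharmacokinetics and Dosing Simulation for Piperacillin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of piperacillin in
    patients with Gram-negative bloodstream infections. Implements a closed-form
    one-compartment model with zero-order (infusion) input and a renal covariate
    on clearance, nonparametric maximum-likelihood population estimation on an
    adaptive grid with a proportional-polynomial assay-error model, simulation
    based diagnostics (normalised prediction distribution errors, visual
    predictive checks, weighted residuals), and Monte Carlo probability of
    target attainment and toxicodynamic analysis of intermittent, extended
    infusion and loading-dose regimens across renal-function categories.
    Includes a synthetic-cohort generator emulating sparse therapeutic drug
    monitoring designs so that every pipeline stage can be exercised without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
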