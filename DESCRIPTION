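Package: cbgpk
Title: Population Pharmacokinetics of Cannabigerol and Its Glucuronide in Horses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parent-metabolite population pharmacokinetic analysis of
    cannabigerol (CBG) and its glucuronide (CBG-G) after intravenous and oral
    (micellar and oil) dosing in horses. Implements the two-compartment parent
    plus one-compartment metabolite model with Weibull time-dependent oral
    absorption as a compiled ODE kernel, a nonlinear mixed-effects layer with
    inter-individual and inter-occasion variability and a formulation
    covariate, SAEM estimation with a fixed metabolized fraction,
    non-compartmental exposure summaries, Monte Carlo multiple-dose regimen
    simulation, and model diagnostics (VPC, weighted residuals). Includes a
    synthetic-study generator emulating the crossover design for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
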