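Package: prait
Title: Population Pharmacokinetics and Dosimetry for Pretargeted
    Radioimmunotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the pharmacokinetic and dosimetric analysis of
    two-step pretargeted radioimmunotherapy, in which a bispecific
    anti-tumour/anti-hapten antibody is infused first and a radiolabelled
    bivalent hapten second.  Provides closed-form two-compartment kinetics
    under zero-order infusion input, body-surface-area scaling of the
    central volume, power-law covariate models linking hapten clearance to
    the hapten/antibody molar ratio, a global two-stage population
    estimator with lognormal random effects, whole-body and organ uptake
    models, MIRD-style absorbed-dose estimation with mass-scaled S
    factors, isotope translation between imaging and therapy
    radionuclides, nonparametric session and cohort comparisons, and a
    seeded virtual-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
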