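Package: kpuu
Title: Brain Drug Distribution from Transwell Equilibrium Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of the extent of brain drug distribution from in
    vitro Transwell experiments with MDCKII-MDR1 cell monolayers. Computes
    apparent permeability coefficients, efflux ratios and mass-balance
    recoveries from bidirectional transport assays; measured and
    dilution-scaled (Austin relation) unbound fractions from equilibrium
    dialysis; equilibrium Kp,brain and unbound partition coefficients
    (Kp,uu,brain) with brain-penetration classification from long-term
    two-chamber distribution experiments; and in vitro/in vivo concordance
    statistics (log-log regression, twofold agreement, category agreement).
    Includes a mechanistic two-compartment simulator of the transwell
    equilibrium and transport experiments (protein binding, efflux
    asymmetry, monolayer depot, sampling depletion, lognormal noise and
    LLOQ censoring) so every pipeline stage can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
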