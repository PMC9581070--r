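Package: soamod
Title: Mechanistic Site-of-Action Modeling for Antibodies Against Soluble Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates target neutralization by antagonist monoclonal
    antibodies against soluble ligands using a three-compartment
    (plasma, peripheral, site-of-action) ordinary differential equation
    model with mechanistic drug-target binding. Rate constants are
    derived by steady-state-preserving closures so that the two-compartment
    plasma pharmacokinetics and the drug-free target baselines are retained
    exactly. Supports one-arm and two-arm (bivalent) antibody binding, an
    optional competing endogenous ligand in plasma, intravenous bolus and
    first-order subcutaneous dosing regimens, steady-state search, free-target
    coverage metrics, affinity-requirement solving by bisection, parameter
    sweeps and local sensitivity analysis. Ships executable case-study
    fixtures for four soluble cytokine/chemokine targets together with a
    random scenario generator for property testing, a YAML/JSON scenario
    configuration schema and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
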