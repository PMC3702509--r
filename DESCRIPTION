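Package: sprscreen
Title: Surface Plasmon Resonance Fragment-Screening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of surface plasmon resonance (SPR)
    fragment screens of the kind run on multi-spot biosensor instruments.
    Provides the closed-form 1:1 Langmuir interaction model and derived
    quantities (theoretical Rmax, equilibrium response, KD, ligand
    efficiency, dissociation half-life, single-concentration detection
    limit), a synthetic-screen generator with realistic noise, solvent
    and surface-activity structure, sensorgram preprocessing (double
    referencing and DMSO solvent correction), single-concentration hit
    triage against a 3-sigma background threshold with molecular-weight
    and protein-activity normalisation, dose-response confirmation by
    global or local kinetic fitting and steady-state affinity fitting,
    and fragment-library design utilities (property filtering, Tanimoto
    diversity selection, library-versus-hits property comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
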