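Package: synflash
Title: Synchrotron Source Characterization and FLASH Radiotherapy
    Effect Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess storage-ring synchrotron radiation as a
    FLASH radiotherapy beam. Provides closed-form bending-magnet source
    characterization (energy loss per turn, critical energy, the
    K_{5/3} photon spectrum and photon rates), pulse-structure and
    dose-rate arithmetic for ultra-high dose-rate beams, a nine-species
    water-radiolysis reaction-network ODE model whose time-integrated
    peroxyl-radical exposure quantifies normal-tissue damage, a
    dose/dose-rate exposure surrogate, and maximum-likelihood fitting
    of a sigmoid normal-tissue-complication-probability (NTCP) model
    against grouped toxicity observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
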