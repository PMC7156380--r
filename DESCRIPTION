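Package: paleoredox
Title: Coupled Mo-U Isotope Mass Balance and Seafloor Euxinia Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the global extent of euxinic seafloor
    from sedimentary molybdenum and uranium isotope records. Implements
    detrital corrections and iron-speciation screening of shale geochemistry,
    a coupled Mo-U concentration and isotope ocean box model with pseudospatial
    burial scaling over seafloor hypsometry, Monte Carlo global sensitivity
    analysis over uniform parameter priors, compatibility filtering of the
    model ensemble against measured records, and a time-dependent
    reconstruction workflow built on cross-validated LOESS smoothers. A fully
    seeded synthetic-data generator emulates euxinic shale and carbonate
    isotope records for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
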