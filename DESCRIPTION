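Package: opsindecay
Title: Kinetic and Structural Analysis of Visual Opsin Active-State Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the decay of the active (meta II) state of
    visual opsins from time-resolved tryptophan fluorescence: monoexponential
    retinal-release fitting, Arrhenius and Eyring transition-state analysis,
    solvent kinetic isotope effects and Gross-Butler proton-inventory model
    selection, a closed-form model of transducin pool activation by a decaying
    receptor, and grid-based internal-cavity volume and water-capacity
    estimation from protein structures, together with seeded synthetic-data
    generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
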