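Package: raswiring
Title: Tissue-Specific Competitive Ras-Effector Binding Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic modeling of the competitive binding equilibrium
    between active (GTP-loaded) Ras and its effector proteins across human
    tissues. Solves the mass-action steady state for a panel of effectors
    competing for a shared pool of active HRAS/KRAS/NRAS, extends the
    equilibrium with receptor-mediated ('piggyback') membrane recruitment of
    effectors, and provides local and global dissociation-constant
    sensitivity analyses, mutant-scenario network rewiring scores with
    Gaussian sweet-spot fits against cancer mutation frequencies,
    affinity/abundance determinant analyses, effector classification, marker
    based tissue-composition estimates, and a seeded synthetic-data generator
    that reproduces the statistical structure of tissue proteome inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
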