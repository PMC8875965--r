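Package: asblm
Title: Biotic Ligand Model for Arsenate Toxicity with Membrane Surface
    Electrostatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts arsenate (As(V)) toxicity to terrestrial plants by
    interspecies extrapolation of a biotic ligand model (BLM) developed for
    Aliivibrio fischeri. Provides simplified chemical equilibrium speciation
    of hydroponic test media (Davies activity corrections, arsenate and
    phosphate acid-base systems), a Gouy-Chapman-Stern solver for the plasma
    membrane surface electrical potential, the inherent-sensitivity times
    environmental-modulator decomposition of EC50, a linear surface-potential
    correction of predicted EC50, sigmoidal dose-response fitting of root
    elongation assays, and a seeded synthetic-study generator for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
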