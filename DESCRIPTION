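Package: asdsol
Title: Drug-Polymer Solubility Limits from Dielectric Relaxation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the solubility limit of an amorphous drug in a polymer
    matrix from broadband dielectric spectroscopy and calorimetric
    measurements, at ambient and elevated pressure.  Implements
    Havriliak-Negami fitting of dielectric loss spectra, Vogel-Fulcher-
    Tammann extrapolation of structural relaxation times to the glass
    transition, Gordon-Taylor composition inversion of measured Tg values,
    Flory-Huggins solid-liquid (liquidus) modelling of the resulting
    solubility points with constant or temperature-dependent interaction
    parameter, and melting-point-referenced transposition of high-pressure
    data to ambient conditions.  A synthetic-data generator emulates every
    input the pipeline consumes so that all stages are testable without
    experimental spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
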