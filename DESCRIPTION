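Package: silksol
Title: Solution Behaviour and Hydration-Shell Thermodynamics of Silk Fibroin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of aqueous silk-fibroin (native silk feedstock) solution
    data: Debye and Guinier modelling of small-angle scattering curves,
    cumulant analysis of dynamic light scattering autocorrelation traces,
    Gaussian band fitting of amide infrared spectra, turbidity cloud-point
    detection, and a three-parameter thermodynamic model of the protein
    hydration shell. The hydration-shell model is fitted to cloud-point and
    aggregation data via the chemical potential of water in salt solutions
    and predicts gelation temperatures on heating and freezing. Seeded
    synthetic-data generators emulate every input stream so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
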