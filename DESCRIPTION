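Package: pyroalga
Title: Pyrolysis Kinetics, Thermodynamics and Bioenergy Analysis of
    Microalgal Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the thermochemical characterization of microalgal
    biomass from multi-heating-rate thermogravimetric (TGA) records:
    conversion and DTG processing with Savitzky-Golay smoothing and
    pyrolysis-zone annotation, four isoconversional ("model-free")
    activation-energy estimators (Friedman, Flynn-Wall-Ozawa,
    Kissinger-Akahira-Sunose, Popescu), combined-kinetics
    (Sestak-Berggren) model fitting with master-plot mechanism ranking,
    activation thermodynamics (enthalpy, Gibbs energy, entropy of
    activation), CO2-biofixation and higher-heating-value calculators
    from ultimate analysis, and a small feed-forward neural surrogate
    for the activation-energy surface. A pseudo-component
    devolatilization simulator provides ground-truth synthetic TGA
    records for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
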