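Package: vesiscope
Title: Multiscale Characterization of Lipid Vesicles in Polymer Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of soft-matter characterization data for lipid-vesicle
    suspensions in polymer (crowder) solutions. Fits dynamic light scattering
    correlograms with single-exponential decays and converts relaxation rates
    to diffusion constants and hydrodynamic sizes via the Stokes-Einstein
    relation; detects lamellar Bragg peaks in small-angle X-ray scattering
    profiles and classifies vesicle lamellarity; integrates differential
    scanning calorimetry exotherms for transition temperatures and specific
    enthalpies; compares suspension viscosities with Einstein and
    Krieger-Dougherty hard-sphere models using volume fractions computed from
    bilayer geometry; and fits time-correlated single-photon-counting decays
    with biexponential models to estimate bilayer microviscosity through a
    Forster-Hoffman calibration. A deterministic synthetic-data generator
    produces instrument-like traces for every stage so the whole pipeline can
    be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
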