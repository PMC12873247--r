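Package: neochron
Title: Bayesian Radiocarbon Chronologies for Fossil Collection Units
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds calibrated, Bayesian phase-model chronologies for
    geochronologically dated fossil collection units in the style used by the
    Neotoma Paleoecology Database. Calibrates radiocarbon dates against an
    IntCal-format curve, fits a uniform-phase Bayesian model (the OxCal
    Phase/Boundary/Sequence construction) by Markov chain Monte Carlo,
    extracts 'event' and 'bounds' chronologies from the posterior, infers
    age ranges for undated analysis units from stratigraphic relationships,
    and writes Neotoma-schema chronology, sample-age, and chron-control
    tables. Includes a synthetic-data generator with known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
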