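Package: cryocurve
Title: Thermodynamic Ice Curves and Physical Properties of Frozen
    Dessert Model Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the freezing behaviour of aqueous anti-freeze-agent
    solutions (sugars, polyols, alcohols, salts) used in frozen desserts.
    Implements colligative freezing-point depression, a hydration-corrected
    equilibrium ice-content curve with a closed-form inversion for the
    effective hydration number, serum-phase freeze concentration, conversion
    of differential scanning calorimetry (DSC) endotherms to ice contents,
    extraction of melting-curve parameters (lag time, melting rate, onset
    temperature) and penetration hardness from instrument-style time series,
    and seeded synthetic-data generators emulating DSC and melting-test
    measurements for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
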