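Package: asirisk
Title: Probabilistic Risk Assessment of Inorganic Arsenic Exposure in
    Infants and Toddlers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo exposure and risk assessment of dietary inorganic
    arsenic for infants and toddlers (4-24 months) from rice cereal,
    drinking water, infant formula and other solid foods. Computes average
    daily doses by age band and source, chronic daily intake, lifetime
    average daily dose, acute and chronic hazard quotients, incremental
    lifetime cancer risk, and a back-calculated maximum contaminant level
    for inorganic arsenic in rice cereal given all other exposure sources.
    Ships the full published parameterization (concentration distributions,
    age-banded body weights and intake volumes, toxicology constants) as a
    validated configuration, plus scenario tools (degenerate point-mass
    scenarios with an independent closed-form oracle, perturbed scenarios)
    for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
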