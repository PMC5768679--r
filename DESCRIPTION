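Package: poolchem
Title: Tide-Pool Carbonate Chemistry, Ecosystem Metabolism and Biophysical Feedbacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-tide biogeochemistry of rocky intertidal
    pools: a seawater CO2-system solver on the total pH scale (equilibrium
    constants, speciation from pH/TA and TA/DIC pairs, aragonite saturation
    state), alkalinity-anomaly net ecosystem calcification (NEC) and
    DIC-budget net community production (NCP) with air-sea CO2 gas exchange,
    community-composition and physical-attribute summaries, mixed-effects
    driver and feedback regressions, and a forward simulator of closed
    tide-pool diel chemistry with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
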