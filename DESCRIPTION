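Package: respcrit
Title: Respirometry, Critical Oxygen Levels and Closed-Chamber Carbonate
    Chemistry for Fish Hypoxia Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying hypoxia tolerance in fishes from
    respirometry data. Converts dissolved-oxygen measurements among the
    units used in the literature (kPa, mmHg/torr, percent air saturation,
    mg/L, umol/L) using Garcia-Gordon oxygen solubility; computes oxygen
    uptake rate (MO2) from closed, flow-through and intermittent-flow
    respirometry traces; estimates standard/routine metabolic rate and the
    critical oxygen level (Pcrit) by broken-stick segmented regression,
    regulation-line intersection, or saturating nonlinear fits; models
    CO2 accumulation in a closed respirometer with a seawater
    carbonate-system solver on the NBS pH scale; and provides a
    harmonisation and statistical pipeline (climate-zone ANOVA with Sidak
    post hoc tests, within-species method comparisons, freshwater versus
    seawater Mann-Whitney tests, stepwise multiple regression) for Pcrit
    trait databases, together with seeded synthetic-data generators that
    emulate oxyregulating and oxyconforming fish.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
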