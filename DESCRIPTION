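Package: mitolifespan
Title: Longitudinal Cellular Bioenergetics and Replicative Lifespan Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts plate-based extracellular-flux measurements (oxygen
    consumption and extracellular acidification rates from MitoStress-style
    injection protocols) into ATP production rates attributed to oxidative
    phosphorylation and glycolysis, with explicit stoichiometric constants
    and per-well quality control. Provides replicative-lifespan analytics
    (population doublings, Hayflick limit rules, windowed group contrasts,
    mixed-effects trajectory tests, aging-rate slopes), qPCR marker pipelines
    (mtDNA copy number by the delta-Ct method with triplicate QC, telomere
    T/S ratios with standard curves, Dixon's Q and duplicate reconciliation,
    cell-free DNA ratios), mtDNA deletion-burden summaries, cohort-level
    effect-size utilities (Hedges' g, Weir-equation resting energy
    expenditure), and seeded synthetic-data generators with known ground
    truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
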