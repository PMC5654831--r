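Package: shotgunlipidr
Title: Shotgun Lipidomics Quantification and Diet-Response Lipidome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for direct-infusion (shotgun) lipidomics of
    skeletal muscle: parsing of lipid shorthand nomenclature and construction
    of a target species database with elemental compositions and monoisotopic
    masses; simulation of class-specific precursor and neutral-loss scan peak
    lists for a multi-strain, two-diet mouse cohort; spectral processing with
    smoothing, signal-to-noise filtering, database matching and two-stage
    isotope correction; absolute quantification against class-specific
    internal standards including the ether-phosphatidylethanolamine response
    factor; resolution of isobaric phospholipid molecular species from
    negative-mode fatty-acyl precursor scans; derived membrane-composition
    metrics (class totals, PC/PE ratio, n-3/n-6 and PUFA category sums,
    diet-induced deltas); and the significance pipeline of log transformation,
    per-species one-way ANOVA screening and protected Fisher's LSD post-hoc
    testing with directional change counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    optparse,
    jsonlite
Config/testthat/edition: 3
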