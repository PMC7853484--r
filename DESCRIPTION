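Package: exine
Title: Pollen Exine Rupture Kinetics and Mock-Community Metabarcoding Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying mechanical rupture of the pollen exine and
    for benchmarking plant DNA metabarcoding against mock communities of known
    composition. Intact-grain count series from bead-milling trials are
    converted to fraction-intact survival curves and fitted with a
    one-parameter exponential decay model, from which projected times to any
    rupture percentage and the optimal bead size per species are derived.
    Species-assigned amplicon read-count tables are evaluated by
    replicate-based presence calling, species retrieval counts, cumulative
    deviation from the equimolar expected proportion, optimal-treatment
    ranking, and per-species trend classification across rupture treatments.
    A seeded synthetic-data generator emulates Poisson counting noise,
    exponential rupture decay, and multinomial read counts with species- and
    marker-specific amplification bias, rupture-dependent template
    accessibility, lysis-time effects and total-dropout species, so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
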