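Package: racocos
Title: Range-Constrained Co-Occurrence Simulation for Presence-Absence Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Null-model analysis of species co-occurrence for spatially
    structured, partially allopatric taxa. Geographic ranges are represented
    as probabilistic occurrence surfaces built from a logistic distance-decay
    spatial weight matrix, and simulated presence-absence matrices are drawn
    by unequal-probability selection under those range constraints, with
    optional hard and soft corrections for uneven sampling effort. Observed
    pairwise and group-cumulated co-occurrence counts are tested against
    Monte-Carlo min-mean-max envelopes. Includes a synthetic-data generator
    for clustered sites, kernel-shaped ranges, skewed sampling effort and
    imposed pairwise exclusion, plus data-quality diagnostics and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
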