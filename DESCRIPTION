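Package: iohdef
Title: Data-Driven Selection of Intraoperative Hypotension Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing candidate definitions of intraoperative
    hypotension (IOH) by their association with 30-day mortality, hospital
    length of stay, and post-anesthesia care unit length of stay. Implements
    artifact cleaning of intraoperative blood-pressure records, interpolation
    to a homogeneous 15-second mean-arterial-pressure grid, a registry of
    sustained/cumulative lowest-MAP and time-below-threshold exposure
    metrics, winsorized natural-cubic-spline regression models with
    spike-at-zero indicators, repeated cross-validated Brier/MSE model
    selection with Akaike-weight confidence sets, and an independent
    estimation stage producing adjusted effect curves and variable
    contributions. A synthetic perioperative cohort generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
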