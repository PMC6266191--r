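Package: tiescope
Title: Sensitivity Analysis of Tie and Characteristic Definitions in
    Roster-Based Social Network Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives social networks from roster-style questionnaire ratings
    under user-declared, named tie definitions (reciprocity, per-direction,
    sum and mean weight thresholds), scores the Alcohol Use Disorders
    Identification Test (AUDIT and AUDIT-C) and classifies individuals under
    competing published cut-off rules, then runs the full cross-product of
    tie definitions by characteristic definitions and compares the resulting
    networks and label assignments (edge Jaccard, agreement, Cohen's kappa).
    Every derived edge and label carries an explanation trace recording the
    conditions evaluated. Includes a seeded generator of synthetic classroom
    studies with planted friendship groups and a drinking-homophily knob, a
    pseudonymization facility, and GraphML/GEXF/CSV exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
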