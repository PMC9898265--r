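Package: dnbr
Title: Dynamic Network Biomarker Analysis for Time-Course Expression Data
Version: 0.1.0
Authors@R: person("dnbr", "maintainers", email = "dnbr@example.org",
    role = c("aut", "cre"))
Description: Detects the triggering phase of a critical state transition in
    replicated time-course expression data using the dynamic network
    biomarker (DNB) framework: per-timepoint group statistics (within-group
    standard deviation, within-group and group-to-background absolute
    Pearson correlation), the criticality index CI = sqrt(size) *
    (PCC_in/PCC_out) * SD_in, dominant-group search by hierarchical
    clustering of co-expression, critical-timepoint detection, and an
    integrated network-degree plus pathway-hit ranking of DNB members.
    Includes a one-factor Gaussian simulator with a planted DNB group and
    transition timepoint for end-to-end validation, a Welch one-vs-rest
    differential-expression candidate screen with Benjamini-Hochberg
    adjustment, readers/writers for delimited expression matrices, GMT gene
    sets and edge-list networks, and a scriptable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
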