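Package: permasens
Title: Emergent Soil-Carbon Temperature Sensitivity, Warming Meta-Analysis,
    and Transfer-Entropy Process Networks for Permafrost Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how permafrost-region soil organic carbon
    (SOC) responds to short-term (step) versus multi-decadal (ramp) warming.
    Provides a reduced-complexity, carbon-conserving daily simulator of
    coupled plant-microbe-soil dynamics over a seasonally frozen soil column
    (four Alaskan site archetypes); a depth-resolved emergent temperature
    sensitivity metric for SOC stocks with a frozen-layer mask; a
    log-response-ratio meta-analysis with inverse-variance pooling and
    forest-table output; and a discrete transfer-entropy process-network
    analysis with shuffle-based significance testing. An orchestration layer
    runs the full step-versus-ramp experiment deterministically from a single
    master seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
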