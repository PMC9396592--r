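Package: causalloop
Title: Assembly and Structural Analysis of Causal-Loop Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, validating and analysing causal-loop
    diagrams (CLDs) of the kind used in qualitative system dynamics and
    participatory group model building. Models are provenance-tagged signed
    digraphs assembled from coded causal-link tables; the package enumerates
    and classifies feedback loops (reinforcing/balancing), detects exogenous
    drivers and hubs, matches system-archetype templates such as drifting
    goals, maps model features and intervention candidates onto Meadows's
    twelve-level leverage-point hierarchy, reads and writes elements and
    connections tables, blueprint JSON and GraphViz DOT, and generates
    synthetic diagrams with planted structure for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
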