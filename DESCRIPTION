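Package: ms2plan
Title: Acquisition-Path Planning for Targeted MS2 in Untargeted LC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans time-ordered MS2 acquisition paths from a preliminary
    MS1 full-scan run. Raw MS1 signals are clustered around detected
    feature apexes, a split-node directed acyclic graph is built whose
    weight-1 edges are feasible above-threshold acquisition windows, and
    dynamic programming over a topological order finds the path that
    fragments the largest number of distinct features. Iterative feature
    exclusion yields inclusion lists for multiple targeted injections.
    Includes a synthetic LC-MS run generator and a minimal top-N
    data-dependent acquisition simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
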