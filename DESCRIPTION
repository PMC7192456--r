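Package: dormabreak
Title: Chill-Unit Models and Coexpression Hub-Gene Analysis for Bud Dormancy Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the release of rhizome bud dormancy by
    chilling. Estimates per-temperature chill units from replicated sprouting
    time-courses, fits a quadratic chill-unit model with derived optimum,
    maximum and upper-limit temperatures, computes chilling accumulation over
    arbitrary temperature schedules, fits stage-wise models linking chilling
    accumulation to sprouting percentage and verifies their predictions.
    Includes a from-scratch weighted gene coexpression analysis (soft
    threshold selection, adjacency, topological overlap, module detection,
    module eigengenes, module-trait correlation, gene significance and module
    membership) with a degree-based hub-gene screen, plus synthetic-data
    generators with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
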