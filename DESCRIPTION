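Package: swimfit
Title: Swim-Tunnel Respirometry, Swimming Economy and Exercise-Growth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for swim-tunnel respirometry experiments on small
    fish: converts closed-phase oxygen traces into mass-specific oxygen uptake
    rates, computes critical swimming speed (U_crit) from incremental-velocity
    trials by the Brett interpolation, fits the quadratic oxygen-uptake vs speed
    model to extrapolate standard metabolic rate, derives cost of transport and
    the optimal swimming speed at its minimum, compares pre/post morphometrics
    between exercised and resting cohorts, and quantifies muscle growth marker
    expression from triplicate qPCR Ct plates by the 2^-ddCt relative
    quantification method with Grubbs outlier screening and Mann-Whitney group
    tests. A seeded synthetic-data generator with known ground truth emulates
    every input so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
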