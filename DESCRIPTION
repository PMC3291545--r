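Package: waterplace
Title: Hydration-Site Prediction and Water-Displacement Classification in
    Protein Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts ordered-water positions in protein binding pockets by
    filtering and clustering ensembles of docked water poses, scores each
    predicted hydration site with a refit hydrogen-bond energy model together
    with heuristic hydrophilicity and lipophilicity descriptors, and
    classifies sites as conserved or displaced (and displaced by polar or
    non-polar ligand groups) using bagged classification trees.  Includes the
    benchmarking machinery for consensus-water validation sets, a
    random-placement baseline, all-subsets AIC model mining with grouped
    cross-validation, ligand displacement-propensity profiles, and synthetic
    fixture generators that exercise the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
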