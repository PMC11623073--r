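Package: locustlens
Title: Country-Partitioned K-Nearest-Neighbour Prediction of Desert Locust Swarm Presence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuses point-event desert locust swarm sightings with monthly
    gridded climate (precipitation, maximum temperature, soil moisture) into a
    labelled presence/absence table, generating pseudo-absences as the calendar
    complement of reported attacks, and predicts locust presence with a
    country-partitioned K-nearest-neighbour classifier (LocustLens). Includes a
    seeded synthetic-data generator with planted country-specific climate
    signal, a from-scratch weighted-Minkowski K-NN with deterministic tie
    handling, stratified cross-validation, randomized hyperparameter search,
    classification metrics with exact rank-based AUC, and an operational
    energy/carbon ledger for the compute phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
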