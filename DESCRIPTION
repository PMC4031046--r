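Package: hooplearn
Title: Spatial Generalization in Operant Learning from Basketball Shot
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how the outcome of one basketball field-goal attempt
    changes the spatial distribution of a player's subsequent attempts within
    the same game.  Estimates per-player outcome-conditioned shot-location
    probabilities and the derived learning matrix at 16-region and coarse
    (3pt / long-2pt / short-2pt) resolution, clusters court regions by
    prospective (row) and retrospective (column) similarity with Ward
    linkage, runs Monte-Carlo permutation tests against surrogate sequences
    drawn from each player's prior, computes distance-resolved learning and
    shooting-percentage curves, and evaluates matching-law statistics of
    2pt/3pt shot allocation.  Includes a sequential-choice generative model
    of shot sequences with a planted generalization kernel and an exact
    Markov-chain oracle for every statistic the pipeline estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
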