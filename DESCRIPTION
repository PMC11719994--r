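Package: ncscreen
Title: Virtual Screening of Food-Derived Natural Compounds Against
    Disease Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for prioritising food-derived natural
    compounds against disease-related protein targets. Trains per-target
    random-forest pIC50 regressors on circular (Morgan-style) molecular
    fingerprints, filters the training domain by a residual-percentile
    applicability cutoff, matches candidate compounds to known actives by
    cosine similarity, clusters candidates with elbow/silhouette model
    selection, summarises structure-activity relationships by potency
    tier (maximum common substructure and functional-group analysis),
    scores blood-brain-barrier permeability with a five-criterion
    physicochemical rule set, and aggregates predicted hits by food
    source. Structure handling (SMILES parsing, canonicalisation,
    physicochemical descriptors, SMARTS matching) is delegated to
    OpenBabel through ChemmineR/ChemmineOB; a seeded synthetic-fixture
    generator with planted structure-activity signal makes every stage
    testable without external chemical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
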