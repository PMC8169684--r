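Package: herbiscreen
Title: Virtual Screening for Herbicide-Likeness and Phytotoxicity Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stepwise in silico screening platform for characterizing small
    molecules as potential herbicides. Computes MACCS structural fingerprints
    and physicochemical descriptors from SMILES, clusters compounds in Tanimoto
    space with internal and external validation indices, trains multi-class
    mode-of-action and weed-selectivity classifiers (random forest by default)
    with grid-search cross-validation, gates predictions with structural and
    physicochemical applicability domains, applies a rule-based
    herbicide-likeness filter, and composes these stages into a screening
    cascade. Includes a synthetic compound-set generator so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    cluster,
    e1071,
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    caret,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
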