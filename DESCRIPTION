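Package: attemptnlp
Title: Classifying Past-Year Suicide Attempt from Clinical Note Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying past-year suicide attempt among
    psychiatrically hospitalized adolescents from pre-admission electronic
    health record notes. Converts free note text to UMLS-style concept codes
    with rule-based negation, builds a note-by-concept dummy matrix, selects
    features per cross-validation fold by random-forest Gini importance
    combined with a curated clinical term list, classifies notes with a
    300-tree random forest, aggregates note calls to patient level over a
    grid of proportion-of-notes cutoffs, selects the operating cutoff by
    5-fold cross-validation, and evaluates on a held-out patient set.
    Includes a synthetic-corpus generator emulating the statistical structure
    of the protected source data so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ranger,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
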