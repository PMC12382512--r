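Package: shortform
Title: Semantic-Embedding Short Forms for Multi-Item Psychological Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and validating short forms of multi-item
    psychological scales. Implements a data-independent reduction method that
    clusters items by the semantic embeddings of their text and keeps the items
    nearest each cluster centroid, alongside three response-data-driven
    baselines: classical item-total selection, principal-component loading
    selection, and a genetic algorithm driven by a graded response model
    (marginal maximum likelihood EM). Includes Hungarian cluster-to-factor
    alignment, silhouette diagnostics, Cronbach's alpha and convergent-validity
    reporting, feed-forward and linear score prediction, and a synthetic-data
    generator with known factor and cluster structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
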