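Package: econclust
Title: Asset-Based Economic Clustering for Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects the small set of categorical household-asset questions
    whose survey-weighted k-medoids (PAM) clustering best partitions a
    population survey into distinct economic groups, using Gower
    dissimilarity over de-duplicated asset-answer profiles and weighted
    average silhouette width for model selection.  Fitted models can be
    condensed into fewer, ordinally ranked wealth groups by agglomerative
    hierarchical clustering of scaled per-cluster outcome means (child
    height-for-age Z-score, women's literacy, proportion of children
    deceased), validated with design-based weighted ANOVA, eta squared and
    adjacent-group t tests, and used to assign new survey or registry
    participants to economic groups by medoid matching with a two-stage
    tie-break.  Includes a reproducible synthetic-survey generator with
    planted economic groups for end-to-end testing without access to
    restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
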