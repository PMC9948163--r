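Package: chemlandscape
Title: Chemical Space, Scaffold Diversity and Structure-Activity Landscape
    Analysis of Bioactivity Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for the cheminformatic analysis of
    ChEMBL-style IC50 bioactivity tables: record curation (essential-value
    filtering, molecule-level deduplication, pIC50 computation, four-class
    potency labeling, steroid flagging), physicochemical chemical-space
    exploration with Mann-Whitney group comparisons and principal component
    analysis, Bemis-Murcko scaffold and cyclic-skeleton diversity metrics
    with scaffold enrichment factors and R-group decomposition,
    structure-activity landscape characterisation (SAS maps, SALI values,
    activity cliffs, consensus cliffs and cliff generators over ECFP4,
    MACCS and PubChem-style fingerprints), and a multiclass QSAR
    classification bench with class rebalancing, feature selection and
    one-vs-rest evaluation. A synthetic bioactivity-data generator with
    known ground truth makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    e1071,
    rpart,
    class,
    randomForest,
    ranger,
    xgboost,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
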