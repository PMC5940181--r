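Package: ddilink
Title: Link Prediction on Drug-Drug Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts potential drug-drug interactions (DDIs) by casting link
    prediction on DDI networks as binary classification of drug pairs. Provides
    eight topological pair-similarity indices (common neighbours, Jaccard,
    Adamic-Adar, preferential attachment, resource allocation, and the
    community-aware CCN, CRA and WIC indices), four semantic similarities
    (IDF-weighted cosine over ATC, MeSH and side-effect code sets, and Tanimoto
    similarity over binary chemical fingerprints), an unsupervised combined
    z-score classifier with a percentile threshold, a supervised classifier
    harness (classification tree, k-nearest neighbours, linear-kernel SVM,
    random forest, gradient boosting) with cross-validated tuning, evaluation
    metrics (precision, recall, F1, AUROC, AUPR), Friedman and Nemenyi rank
    comparison of classifiers across networks, and a synthetic DDI-network
    generator with planted communities and correlated drug attributes for
    end-to-end testing without access to the licensed source databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    rpart,
    class,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
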