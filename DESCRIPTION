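Package: RankVS
Title: Learning-to-Rank Methods for Ligand-Based Virtual Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate compounds against protein targets with
    learning-to-rank models. Provides point-wise (PRank), pair-wise
    (RankNet, RankBoost, ranking SVM) and list-wise (AdaRank, ListNet)
    rankers plus a support-vector-regression baseline under one
    query-grouped fit/score contract; composition/transition/distribution
    (CTD) protein sequence descriptors and two target-compound feature
    mappings (side-by-side concatenation and the Kronecker cross-term);
    NDCG@k evaluation; five-level affinity grading and dataset curation
    filters; four cross-target and heterogeneous-data experiment
    strategies; and a seeded bilinear synthetic-data generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, jsonlite, yaml, Biostrings, e1071,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, ChemmineR, ChemmineOB, knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Cheminformatics, Proteomics, MachineLearning
RoxygenNote: 7.3.3
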