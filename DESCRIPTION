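Package: mppsig
Title: Metabolic Pathway Pairwise Signatures for Blood-Based Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds within-sample metabolic pathway pairwise (MPP) signatures
    from bulk transcriptomes: single-sample gene-set enrichment (ssGSEA)
    pathway activities, pairwise ordering indicators, a chi-square/Holm
    differential screen, consensus non-negative matrix factorization (Brunet
    KL) patient subtyping, maximal clique centrality hub-pathway networks,
    and an L1-penalized logistic risk score (MPPSS) for case/control
    classification, together with a synthetic-data generator that plants
    group effects and subtypes so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    glmnet,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
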