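Package: thalnet
Title: Structural Covariance Network Analysis of Cortical-Thalamic Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and compares group-level structural covariance networks
    from regional brain volumes, with an emphasis on thalamic nuclei and
    cortical lobes. Provides ingestion and interquartile-range quality control
    of subject-level volume tables, aggregation of fine parcellations (25
    thalamic nuclei per hemisphere, 68 Desikan-Killiany cortical regions) to a
    22-node cortical-thalamic network, covariate residualization (age, sex,
    intracranial volume), Pearson correlation networks with negative edges
    zeroed, weighted graph measures (efficiency, clustering, transitivity,
    modularity, small-worldness and their nodal counterparts), label
    permutation tests with Benjamini-Hochberg false discovery rate control,
    volumetric ANCOVA and Spearman association stages, and a latent-factor
    synthetic cohort generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
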