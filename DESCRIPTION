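Package: edphenotype
Title: Computational Phenotyping of Opioid-Related Emergency Department
    Presentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers data-driven phenotypes of opioid-related emergency
    department (ED) encounters from electronic health record (EHR) extracts.
    Clinical concepts are extracted from note text with a deterministic
    longest-match lexicon, merged with structured-data tokens (diagnosis
    groups, medication classes, and laboratory values carrying "high"/"low"
    modifiers at two standard deviations from a matched background cohort),
    filtered by a two-cohort document-frequency rule and a chi-square
    keep-word test, and modelled with latent Dirichlet allocation fitted by
    collapsed Gibbs sampling. Encounters are embedded on the topic simplex,
    clustered with K-means (silhouette and Dunn validation), and each
    cluster is profiled by Kaplan-Meier survival, Charlson comorbidity
    index, ED-return and medication rates, and relative risks. A synthetic
    EHR generator with planted topics, clusters, and outcomes makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
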