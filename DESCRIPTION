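Package: caniact
Title: Causal DAG-Guided Mixed-Model Analysis of Dog Activity Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for population-scale analysis of accelerometer-measured
    physical activity in pet dogs linked to veterinary electronic health
    records. Provides a causal directed acyclic graph toolkit (d-separation,
    minimal backdoor adjustment sets, implied conditional independences and
    their data-consistency tests), a two-source synthetic cohort generator
    with recorded ground truth, deterministic record linkage with a
    closest-prior-visit join and a configurable filter cascade, derived
    clinical covariates (body-condition-corrected breed size, weight status,
    visit health classification), linear mixed models on log active minutes
    with repeated-subsample aggregation inference and marginal means, a
    boosted-tree flexible-model validation, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
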