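Package: epemix
Title: Entropy-Penalized EM Clustering of Sex-Dimorphic Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sex-dimorphic temporal transcriptomes from
    longitudinal bulk expression studies. Provides a differential-expression
    screen for a signed sex signature (pooled-variance t tests with
    Benjamini-Hochberg control), entropy-penalized EM fitting of a mixture of
    polynomial mixed-effects models to gene-by-sex expression time courses
    (cluster-level cubic fixed effects, gene-level quadratic random effects)
    with automatic selection of the number of clusters, cross-tabulation of
    male versus female cluster labels into concordant and discordant gene
    sets, hypergeometric gene-set overrepresentation, and an
    openSESAME-style signature-association scan of an expression compendium.
    A synthetic-data generator reproduces the assumed generative model so
    every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
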