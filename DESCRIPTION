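Package: tmectx
Title: Tumour Immune Microenvironment Contexture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the immune contexture of solid tumours from
    segmented multiplex-immunohistochemistry cell tables and labelled
    tissue masks: compartment cell densities per square millimetre,
    anti- versus pro-tumour cell ratios, PD-L1 area positivity, and
    tumour-core versus tumour-margin infiltration profiles measured as
    distance from the infiltrative tumour border. Companion tools
    normalize immune gene-expression panels against housekeeping genes,
    score cell types and pathways from marker gene sets, cluster samples
    into immune phenotypes, and run differential expression with
    Benjamini-Hochberg correction. Survival inference covers
    Kaplan-Meier estimation, log-rank tests, univariate Cox models and
    cutpoint selection by maximally selected rank statistics with
    permutation or asymptotic p-values. A synthetic-cohort generator
    with controllable spatial exclusion gradients, archetype expression
    effects and proportional-hazards event times makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
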