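Package: gsconsistency
Title: Consistency Metrics for Gene-Set Collections in Expression Compendia
Version: 0.1.0
Authors@R: person("R.", "Holwerda", email = "rholwerda@example.org",
    role = c("aut", "cre"))
Description: Evaluates how consistently the member genes of annotated gene
    sets (GO terms, KEGG maps, predicted operons, SEED subsystems, scenarios
    and paths, or user-defined groupings) behave across compendia of
    normalized log2-scale expression arrays. Implements seven per-set
    consistency metrics with their array-pair and gene subsampling
    estimators, hierarchy-propagated gene-set construction, cross-source
    comparison analyses (direction-aware source ranking, metric
    intercorrelation, size-stratified profiles, nested linear models), and a
    synthetic compendium generator with an analytic within-set correlation
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
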