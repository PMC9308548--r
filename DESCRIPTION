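Package: methego
Title: Differential DNA Methylation Calling and Ego-Network Biomarker Ranking
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for abnormal DNA methylation analysis on
    beta-value arrays: probe quality-control filtering, beta-mixture quantile
    normalization of design-class-II probes, two-stage differential
    methylation calling with Welch t-tests and Benjamini-Hochberg correction,
    hierarchical clustering of samples, Fisher's-exact gene-set enrichment,
    ego-network scoring of candidate genes on a gene-interaction subnetwork
    (correlation-gated significance weights, context likelihood of
    relatedness, z-score ranking), and linear support-vector-machine
    validation of the selected ego genes.  Includes a synthetic-data
    generator that emulates the beta-value array design with planted
    differential probes, a scale-free interaction network carrying a planted
    disease module, and enriched gene sets, with ground truth for every
    downstream stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
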