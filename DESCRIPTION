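Package: indigoferm
Title: Downstream Analysis of Indigo-Reduction Fermentation Microbiota Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of 16S amplicon time series from
    sukumo (composted indigo plant) dyeing-vat fermentations. Implements the
    dyeing-intensity colour metric from CIE L*a*b* measurements, Nernst-based
    pH adjustment of electron-mediator midpoint potentials and feasibility
    classification against the indigo reduction threshold, relative-abundance
    and alpha-diversity processing, subpathway-ratio selection and taxon-level
    functional contribution decomposition of predicted gene-family tables,
    a centred log-ratio correlation screen of gene families against dyeing
    intensity, Spearman co-occurrence network inference over genus abundance
    trajectories with exact small-sample permutation p-values, and scanning of
    annotated genomes for the flavin-based extracellular electron transfer
    gene catalogue. A seeded synthetic-data generator emulates the big-batch
    (fast ORP drop) and small-batch (slow ORP drop) fermentation designs so
    every stage can be exercised against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
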