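Package: innateTolerance
Title: Classification of Tolerizeable and Non-Tolerizeable Genes in
    Restimulated Macrophage Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq experiments in which innate
    immune cells are stimulated twice through pattern-recognition receptors
    (a 24-hour tolerizing stimulus followed by a 1- or 4-hour rechallenge).
    The package normalizes raw counts to reads per million (RPM) with
    zero-to-one replacement, classifies each gene's response to the second
    stimulation with a fold-ratio rule engine that explicitly corrects for
    residual expression left over from the first stimulation (uninducible,
    hypo-/normo-/hyperinducible, late, hyperinducible-2, de novo,
    unresponsive), aggregates the per-timepoint calls into tolerizeable (T)
    versus non-tolerizeable (NT) assessments with sustained-expression (SE)
    and normo/hyperinducible (NH) subcategories, quantifies
    cross-experiment reproducibility of gene classes by a chi-square
    coincidence test, scores transcription-factor-binding-site and gene-set
    enrichment between gene classes with an offset log2 enrichment score
    and an automatic binding-score cutoff scan, and simulates the full
    two-experiment 18-sample design with archetype-labelled genes under a
    negative-binomial noise model so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Classification, ImmunoOncology
RoxygenNote: 7.3.3
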