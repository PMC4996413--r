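Package: epimarker
Title: DNA Methylation Biomarker Discovery with Evolutionary and
    Ontology-Driven Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case-control DNA methylation biomarker
    discovery on two-channel methylation arrays. Implements beta/M/average
    intensity signal summaries with a two-step quality-control-based
    normalization (within-chip intensity-binned error correction followed by an
    across-probe correction), statistical pre-selection of CpG sites by scaled
    coefficient of variation and sign-flip bootstrap-corrected paired t-tests,
    a genetic-algorithm wrapper feature selector with an embedded
    distance-weighted k-nearest-neighbour fitness, a semantic gene-centrality
    selector built on Resnik similarity over a gene ontology graph, a
    classifier suite (weighted k-NN, Gini decision tree, one-hidden-layer
    neural network) with leave-one-out and independent-holdout evaluation, and
    hypergeometric gene-set enrichment with genomic-region distribution
    reporting. A seeded synthetic-cohort generator with planted
    differentially-methylated probes, chip-level technical bias, replicated
    technical quality-control samples and a toy ontology provides recoverable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
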