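Package: neurosig
Title: Neuron-Type-Specific Expression Signatures of Neuromodulatory Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling neuromodulatory gene expression across a
    hierarchical transcriptomic neurotaxonomy, as applied to single-cell
    RNA-seq of mouse hippocampal area CA1. Computes counts-per-million
    normalization, type-mean expression signatures, the delta
    type-specificity statistic (equivalent to the tissue-specificity index
    tau), threshold-based cell-type and gene filtering, per-cell
    co-expression tallies of curated GPCR / ion-channel / neuropeptide gene
    panels, cognate neuropeptide-receptor pairing, within-type outlier
    diagnostics, and subsampling stability of signatures. Includes a
    negative-binomial single-cell simulator with a planted taxonomy and
    known gene specificity classes for end-to-end validation, plus
    publication-style signature heatmaps and co-expression histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
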