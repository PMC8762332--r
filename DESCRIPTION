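Package: structTE
Title: Translational Efficiency and 5'UTR Structure Analysis for Paired
    Ribo-Seq/RNA-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how 5'UTR secondary structure shapes
    translational control in factorial ribosome-profiling designs.
    Computes translation efficiency (TE, the ratio of normalized
    ribosome-footprint to mRNA signal) and per-gene log2 fold-changes
    for strain-by-condition contrasts, classifies fold-change gene sets,
    scores cumulative and per-nucleotide RNA structure (PARS-style) over
    named 5'UTR and CDS windows, tests gene-set overlap (Fisher's exact
    test) and term enrichment (hypergeometric with Benjamini-Hochberg
    correction), and quantifies polysome-to-monosome ratios from
    sucrose-gradient absorbance traces. A negative-binomial simulator
    generates paired count matrices with planted, structure-coupled TE
    effects for end-to-end validation, and a seeded pipeline driver
    writes reproducible report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
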