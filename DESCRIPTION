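Package: hapscreen
Title: Haploid Gene-Trap Screen Analysis with Phenotype-Sorted Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of haploid gene-trap insertional mutagenesis screens
    read out by fluorescence-activated sorting of phenotype tails. Maps
    gene-trap junction reads to a reference tolerating one mismatch,
    classifies insertions against gene models (sense orientation, gene-body
    region), computes per-gene mutational indices with two-sided Fisher's
    exact enrichment tests, compares screens, and draws fishtail plots. A
    synthetic sorted-screen generator with known gene effects supports
    calibration and power analysis without external data. Also provides the
    indirect-calorimetry substrate-oxidation arithmetic (respiratory
    exchange ratio, glucose and fat oxidation, lean-mass correction) and
    shotgun-lipidomics postprocessing (signal-to-noise and blank filtering,
    mol% normalization, condition contrasts) used alongside such screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: FunctionalGenomics, Genetics, StatisticalMethod, Software
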