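Package: cenATkit
Title: Composition Analytics, Design and Statistics for A+T-Rich Centromeres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying why centromeric DNA is often A+T rich, built
    around centromere-replacement experiments in fission yeast. Provides
    composition analytics on DNA sequences (A+T fraction, windowed profiles,
    A/T homopolymer runs, a centromere-competence classifier), construction
    and mutagenesis of candidate centromere sequences (tandem and interleaved
    concatemers, discriminating 4 bp deletion markers, run-disrupting and
    run-preserving composition mutagenesis), CENP-A ChIP enrichment
    quantitation (coverage tracks, reference-centromere normalization,
    marker-based read discrimination, composition-vs-binding regression),
    replacement-assay statistics with zero-event binomial confidence bounds
    and lineage-division accounting, the mutation-selection-balance scaling
    regression of relative centromeric A+T against log genome size, and
    seeded synthetic-data generators with recorded ground truth for every
    input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotated-sequence.R'
    'assay.R'
    'cenATkit-package.R'
    'chip.R'
    'composition.R'
    'design.R'
    'scaling.R'
    'simulate.R'
    'utils.R'
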