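Package: phyloage
Title: Physiological Blood Age from Somatic Variant Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the decay of hematopoietic stem cell (HSC)
    phylogenetic diversity from a somatic variant frequency spectrum (VFS)
    obtained by bulk or colony sequencing, without reconstructing the HSC
    phylogeny.  Implements the lambda metric (sum of variant allele
    frequencies above a tip-variant threshold), the cluster-based gamma
    metric with a binomial-mixture VAF clusterer, and an exponential
    age model that converts lambda into a physiological blood age
    (phyloAge*).  Includes leave-one-out evaluation with age-stratified
    error reporting, read-depth resampling and panel restriction for
    matched-coverage modelling, classical diversity statistics for
    comparison (nucleotide diversity, Tajima's D, Fay and Wu's H, Hill
    numbers, lineage-through-time Shannon diversity), and a forward
    simulator of HSC phylogenies with embryonic diversification and
    age-dependent clonal hematopoiesis that supplies ground truth for
    every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
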