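Package: hapsweep
Title: Haplotype-Based Selective Sweep Scans with Demographic Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of selective sweeps in phased population genomic data,
    calibrated against an explicit demographic null. Implements from-scratch
    extended haplotype homozygosity statistics (EHH, iHS, nSL, XP-EHH, XP-nSL)
    with allele-frequency-bin normalization, the population branch statistic
    built from Hudson's Fst, window-based diversity statistics (nucleotide
    diversity, Tajima's D, d_xy), runs of homozygosity, and a forward-time
    Wright-Fisher simulator of a three-population founder-effect demography
    with migration, secondary contact and optional hard sweeps, used to set
    false-positive-controlled outlier thresholds. Also provides region-level
    GO enrichment by Fisher's exact test and an alignment-free d2s k-mer
    dissimilarity with classical multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
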