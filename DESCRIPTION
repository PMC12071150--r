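Package: bovintro
Title: Population-Genomic Scans for Diversity, Inbreeding, Selection and
    Introgression in Admixed Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic statistics and genome scans for
    admixed bovine whole-genome data: nucleotide diversity, Tajima's D,
    Hudson's FST and linkage-disequilibrium decay; PLINK-style detection of
    runs of homozygosity with unsupervised three-component Gaussian-mixture
    length classification and the FROH inbreeding coefficient; extended
    haplotype homozygosity and iHS selection scans with a normal-tail
    nucleotide-diversity cutoff; and a wild-species introgression toolkit
    (Patterson's D with block-jackknife Z scores, the U-statistic
    adaptive-introgression window scan, and an incomplete-lineage-sorting
    tract-length filter).  A founder-mosaic simulator generates phased
    multi-population panels with planted introgression tracts, autozygous
    segments and selective sweeps so that every scan can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
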