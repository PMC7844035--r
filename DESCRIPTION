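Package: sweepscan
Title: Selection-Signature Scans for Multi-Population Diploid Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic regions under recent selection in multi-population
    diploid panels. Implements windowed pooled heterozygosity (Hp/ZHp),
    windowed Weir-Cockerham FST (ZFst) and the cross-population extended
    haplotype homozygosity statistic (XP-EHH), together with the supporting
    population-genetic toolkit: PLINK-style detection of runs of homozygosity,
    binned linkage-disequilibrium decay, per-population diversity summaries,
    principal component analysis, neighbor-joining trees from p-distances,
    candidate-region extraction with gene annotation, and hypergeometric
    gene-set enrichment. A Balding-Nichols founder-mosaic simulator with
    planted selective sweeps and homozygous segments provides ground truth
    for validating every scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    jsonlite,
    ape,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
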