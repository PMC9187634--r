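Package: sweepscan
Title: Two-Statistic Selective-Sweep Scans on Phased Haplotype Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate selective sweeps between a target and a
    reference population from phased biallelic SNP panels. Implements the
    Weir-Cockerham fixation index in overlapping sliding windows with
    genome-wide Z-standardisation (ZFst), per-SNP cross-population extended
    haplotype homozygosity (XP-EHH) with genome-wide normalisation and
    window averaging, percentile-based candidate calling in both tails,
    cross-statistic window overlap, GTF-based gene annotation of candidate
    regions, and LD-pruned principal component analysis for population
    structure. Ships a two-population Balding-Nichols haplotype simulator
    with founder-mosaic linkage disequilibrium and injectable hard sweeps,
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
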