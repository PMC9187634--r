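test_that("GT parsing yields dosages, haplotype columns and missingness", {
    samples <- c("a", "b", "c")
    vcf <- writeToyVcf(list(
        list(pos = 100, gts = c("0|0", "0|1", "1|1")),
        list(pos = 200, gts = c("./.", "0|0", "1|1")),
        list(pos = 300, gts = c("0|1", "0|1", "0|1"))),
        samples)
    pm <- toyPopmap(samples, c("target", "target", "reference"))
    inp <- readPhasedVcf(vcf, pm)
    d <- dosages(inp$genotypes)
    expect_equal(unname(d[1, ]), c(0L, 1L, 2L))
    expect_true(is.na(d[2, "a"]))
    expect_equal(unname(d[2, c("b", "c")]), c(0L, 2L))
    # panel excludes the record with a missing genotype
    expect_equal(nSites(inp$panels$target), 2L)
    expect_equal(haplotypes(inp$panels$target)[, 1], c(0L, 0L, 0L, 1L))
    expect_equal(haplotypes(inp$panels$reference)[, 1], c(1L, 1L))
})

test_that("unknown samples and unphased called genotypes are errors", {
    samples <- c("a", "b")
    vcf <- writeToyVcf(list(list(pos = 100, gts = c("0|0", "0/1"))),
                       samples)
    expect_error(readPhasedVcf(vcf, toyPopmap("a", "target")),
                 "absent from population map")
    pm <- toyPopmap(samples, c("target", "reference"))
    expect_error(readPhasedVcf(vcf, pm), "unphased.*chr1:100")
})

test_that("hard filters drop sites beyond any present threshold only", {
    samples <- c("a", "b")
    gts <- c("0|1", "0|1")
    vcf <- writeToyVcf(list(
        list(pos = 100, info = "QD=1.9", gts = gts),
        list(pos = 200,
             info = "QD=2;FS=60;MQ=40;MQRankSum=-12.5;ReadPosRankSum=-8;SOR=3",
             gts = gts),
        list(pos = 300, gts = gts),
        list(pos = 400, info = "FS=60.5", gts = gts),
        list(pos = 500, info = "MQ=39.9;QD=30", gts = gts),
        list(pos = 600, info = "MQRankSum=-12.6", gts = gts),
        list(pos = 700, info = "ReadPosRankSum=-8.1", gts = gts),
        list(pos = 800, info = "SOR=3.01", gts = gts)),
        samples)
    pm <- toyPopmap(samples, c("target", "reference"))
    gt <- readPhasedVcf(vcf, pm)$genotypes
    kept <- GenomicRanges::start(SummarizedExperiment::rowRanges(
        hardFilterSites(gt)))
    expect_equal(kept, c(200, 300))
})

test_that("cluster filter removes consecutive triples spanning <= 10 bp", {
    mk <- function(pos) {
        sites <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(pos, width = 1))
        S4Vectors::mcols(sites)$ref <- "A"
        S4Vectors::mcols(sites)$alt <- "G"
        GenotypeTable(matrix(1L, length(pos), 4), sites, paste0("s", 1:4),
                      rep(c("target", "reference"), each = 2))
    }
    keptPos <- function(gt) GenomicRanges::start(
        SummarizedExperiment::rowRanges(gt))
    expect_equal(keptPos(clusterFilter(mk(c(100, 105, 109)))), numeric(0))
    expect_equal(keptPos(clusterFilter(mk(c(100, 105, 111)))),
                 c(100, 105, 111))
    expect_equal(keptPos(clusterFilter(mk(c(100, 101)))), c(100, 101))
    # overlapping triples: 4 SNPs in 10 bp all removed
    expect_equal(keptPos(clusterFilter(mk(c(100, 103, 106, 109)))),
                 numeric(0))
})

test_that("frequency filters apply MAF, call-rate and biallelic rules", {
    samples <- sprintf("s%02d", 1:10)
    gts <- function(...) c(...)
    het1 <- c("0|1", rep("0|0", 9))                     # MAF 0.05
    miss2 <- c(rep("0|1", 4), rep("1|1", 4), "./.", "./.")  # call rate 0.8
    mono <- rep("0|0", 10)
    multi <- rep("1|2", 10)
    vcf <- writeToyVcf(list(
        list(pos = 100, gts = het1),
        list(pos = 200, gts = miss2),
        list(pos = 300, gts = mono),
        list(pos = 400, alt = "G,T", gts = multi),
        list(pos = 500, gts = rep("./.", 10))),
        samples)
    pm <- toyPopmap(samples, rep(c("target", "reference"), each = 5))
    gt <- readPhasedVcf(vcf, pm)$genotypes
    kept <- GenomicRanges::start(SummarizedExperiment::rowRanges(
        frequencyFilters(gt)))
    expect_equal(kept, c(100, 200))
})

test_that("autosome restriction keeps declared chromosomes only", {
    sites <- GenomicRanges::GRanges(c("chr1", "chr1", "chrX"),
        IRanges::IRanges(c(10, 20, 30), width = 1))
    S4Vectors::mcols(sites)$ref <- "A"; S4Vectors::mcols(sites)$alt <- "G"
    gt <- GenotypeTable(matrix(1L, 3, 2), sites, c("a", "b"),
                        c("target", "reference"))
    out <- restrictAutosomes(gt, "chr1")
    expect_equal(as.character(GenomeInfoDb::seqnames(
        SummarizedExperiment::rowRanges(out))), c("chr1", "chr1"))
    expect_identical(nrow(restrictAutosomes(gt, c("chr1", "chrX"))), 3L)
    expect_error(restrictAutosomes(gt, character(0)), "empty")
    expect_error(restrictAutosomes(gt, "chr7"), "no sites")
})

test_that("filters are idempotent and preserve site order", {
    sim <- simulatePanels(SimParams(nTarget = 8, nRef = 8,
        chromLengths = c(chr1 = 2e5), seed = 77))
    gt <- sim$genotypes
    for (f in list(hardFilterSites,
                   clusterFilter,
                   frequencyFilters,
                   function(x) restrictAutosomes(x, "chr1"))) {
        once <- f(gt)
        twice <- f(once)
        expect_identical(dosages(once), dosages(twice))
        pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(once))
        expect_false(is.unsorted(pos))
    }
})

test_that("an engineered 10-record VCF survives with the hand count", {
    samples <- sprintf("s%02d", 1:10)
    ok <- rep(c("0|1", "1|1", "0|0", "0|1", "0|0"), 2)
    vcf <- writeToyVcf(list(
        list(pos = 100, gts = ok),                      # keep
        list(pos = 150, info = "QD=1.5", gts = ok),     # hard filter
        list(pos = 200, gts = ok),                      # keep
        list(pos = 301, gts = ok),                      # cluster (301-309)
        list(pos = 305, gts = ok),                      # cluster
        list(pos = 309, gts = ok),                      # cluster
        list(pos = 400, gts = rep("0|0", 10)),          # monomorphic
        list(pos = 500, alt = "G,T", gts = ok),         # multi-allelic
        list(pos = 600, gts = c(rep("./.", 3), ok[4:10])),  # call rate 0.7
        list(pos = 700, gts = ok)),                     # keep
        samples)
    pm <- toyPopmap(samples, rep(c("target", "reference"), each = 5))
    gt <- readPhasedVcf(vcf, pm)$genotypes
    res <- applySiteFilters(gt, runConfig())
    expect_equal(unname(res$counts),
                 c(10L, 9L, 6L, 3L, 3L))
    expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(
        res$genotypes)), c(100, 200, 700))
})

test_that("aligned panels keep exactly the filtered sites", {
    sim <- simulatePanels(SimParams(nTarget = 6, nRef = 6,
        chromLengths = c(chr1 = 2e5), seed = 9))
    dir <- tempfile()
    out <- simulateToFiles(SimParams(nTarget = 6, nRef = 6,
        chromLengths = c(chr1 = 2e5), seed = 9), dir)
    inp <- readPhasedVcf(out$paths$vcf, out$paths$popmap)
    flt <- frequencyFilters(inp$genotypes, maf = 0.2)
    panels <- alignPanelsToSites(inp$panels, flt)
    expect_equal(nSites(panels$target), nrow(flt))
    expect_equal(GenomicRanges::start(siteRanges(panels$target)),
                 GenomicRanges::start(SummarizedExperiment::rowRanges(flt)))
})
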