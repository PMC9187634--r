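smallParams <- function(...) {
    SimParams(nTarget = 10, nRef = 10, chromLengths = c(chr1 = 5e5),
              snpDensity = 5e-4, seed = 11, ...)
}

test_that("simulation is deterministic: identical params, identical VCF", {
    p <- smallParams()
    f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
    s1 <- simulatePanels(p); s2 <- simulatePanels(p)
    writePhasedVcf(s1$target, s1$reference, f1)
    writePhasedVcf(s2$target, s2$reference, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(haplotypes(s1$target), haplotypes(s2$target))
})

test_that("sites are sorted, unique, 1-based and biallelic", {
    sim <- simulatePanels(smallParams())
    pos <- GenomicRanges::start(siteRanges(sim$target))
    expect_true(all(pos >= 1))
    expect_true(all(diff(pos) > 0))
    expect_equal(sim$truth$siteCount, length(pos))
    expect_true(all(haplotypes(sim$target) %in% 0:1))
})

test_that("F = 0 gives matching population frequency distributions", {
    sim <- simulatePanels(SimParams(nTarget = 50, nRef = 50,
        chromLengths = c(chr1 = 5e6), snpDensity = 1e-3,
        driftF = 0, nFounders = 100, switchRate = 1e-3, seed = 21))
    d <- dosages(sim$genotypes)
    pops <- populations(sim$genotypes)
    pT <- rowMeans(d[, pops == "target"]) / 2
    pR <- rowMeans(d[, pops == "reference"]) / 2
    diffs <- pT - pR
    se <- sd(diffs) / sqrt(length(diffs))
    expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
    # and the drawn truth frequencies are exactly equal
    expect_identical(sim$truth$alleleFreqs$p_target,
                     sim$truth$alleleFreqs$p_reference)
})

test_that("full-carrier noiseless sweep makes target haplotypes identical", {
    sim <- simulatePanels(smallParams(
        sweeps = list(SweepSpec("chr1", 2e5, 3e5, carrierFraction = 1,
                                noiseRate = 0))))
    pos <- GenomicRanges::start(siteRanges(sim$target))
    idx <- which(pos >= 2e5 & pos <= 3e5)
    block <- haplotypes(sim$target)[, idx]
    expect_gt(length(idx), 0)
    expect_true(all(block == rep(block[1, ], each = nrow(block))))
    # EHH within the swept region is 1 throughout
    core <- idx[ceiling(length(idx) / 2)]
    cur <- ehhAtCore(sim$target, core, cutoff = 0.05)
    inReg <- cur$right$pos <= 3e5
    expect_true(all(cur$right$ehh[inReg] == 1))
})

test_that("injectSweep honours carrier fraction exactly", {
    p <- randPanel(20, 30, seed = 3, chromLen = 1e4)
    spec0 <- SweepSpec("chr1", 1, 1e4, carrierFraction = 0)
    expect_identical(haplotypes(injectSweep(p, spec0, seed = 5)),
                     haplotypes(p))
    spec9 <- SweepSpec("chr1", 1, 1e4, carrierFraction = 0.9,
                       noiseRate = 0)
    swept <- injectSweep(p, spec9, seed = 5)
    h <- haplotypes(swept)
    counts <- table(apply(h, 1, paste, collapse = ""))
    expect_equal(max(counts), 18)
    spec1 <- SweepSpec("chr1", 1, 1e4, carrierFraction = 1, noiseRate = 0)
    h1 <- haplotypes(injectSweep(p, spec1, seed = 5))
    expect_true(all(h1 == rep(h1[1, ], each = 20)))
})

test_that("sweep injection leaves sites outside the interval untouched", {
    p <- randPanel(10, 50, seed = 13, chromLen = 1e5)
    pos <- GenomicRanges::start(siteRanges(p))
    spec <- SweepSpec("chr1", 2e4, 5e4, carrierFraction = 1, noiseRate = 0)
    swept <- injectSweep(p, spec, seed = 2)
    outside <- pos < 2e4 | pos > 5e4
    expect_identical(haplotypes(swept)[, outside],
                     haplotypes(p)[, outside])
    empty <- SweepSpec("chr2", 1, 100, carrierFraction = 1)
    expect_error(injectSweep(p, empty, seed = 2), "no sites")
})

test_that("VCF output round-trips exactly through the reader", {
    sim <- simulatePanels(smallParams())
    dir <- tempfile(); out <- simulateToFiles(smallParams(), dir)
    inp <- readPhasedVcf(out$paths$vcf, out$paths$popmap)
    expect_identical(haplotypes(inp$panels$target),
                     haplotypes(sim$target))
    expect_identical(haplotypes(inp$panels$reference),
                     haplotypes(sim$reference))
    expect_identical(dosages(inp$genotypes), dosages(sim$genotypes))
    expect_equal(unname(inp$chromLengths["chr1"]), 5e5)
    # record count equals site count
    expect_equal(sum(!startsWith(readLines(out$paths$vcf), "#")),
                 sim$truth$siteCount)
    # truth files
    expect_true(file.exists(out$paths$bed))
    pj <- jsonlite::read_json(out$paths$json)
    expect_equal(pj$site_count, sim$truth$siteCount)
})

test_that("all-heterozygous sites are written as 0|1 fields", {
    sites <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(10, 20, 30), width = 1),
        seqinfo = GenomeInfoDb::Seqinfo("chr1", 100))
    tgt <- HaplotypePanel(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)), sites,
                          "target")
    ref <- HaplotypePanel(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)), sites,
                          "reference")
    f <- tempfile(fileext = ".vcf")
    writePhasedVcf(tgt, ref, f)
    recs <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
    expect_length(recs, 3)
    gts <- do.call(rbind, strsplit(recs, "\t"))[, 10:11]
    expect_true(all(gts == "0|1"))
})

test_that("invalid simulator parameters are rejected", {
    expect_error(SimParams(driftF = 1), "driftF")
    expect_error(SimParams(nTarget = 1), "2 diploids")
    expect_error(SimParams(chromLengths = setNames(numeric(0),
                                                   character(0))),
                 "chromosome")
    expect_error(SimParams(sweeps = list(SweepSpec("chr9", 1, 10))),
                 "outside")
})
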