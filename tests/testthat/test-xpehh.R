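fullCurve <- function(panel, core) ehhAtCore(panel, core, cutoff = 0,
                                             maxGap = Inf)

test_that("EHH equals exhaustive group enumeration on random panels", {
    for (s in 1:60) {
        nHap <- 2 * sample(1:4, 1) + 2      # 4..10 haplotypes
        nSites <- sample(3:12, 1)
        p <- randPanel(nHap, nSites, seed = 1000 + s)
        core <- sample(nSites, 1)
        cur <- fullCurve(p, core)
        expect_equal(cur$right$ehh,
                     ehhCurveOracle(haplotypes(p), core, "right"))
        expect_equal(cur$left$ehh,
                     ehhCurveOracle(haplotypes(p), core, "left"))
    }
})

test_that("EHH curves are monotone non-increasing outward", {
    for (s in 1:20) {
        p <- randPanel(8, 12, seed = 2000 + s)
        for (core in c(1, 6, 12)) {
            cur <- fullCurve(p, core)
            expect_true(all(diff(cur$left$ehh) <= 1e-15))
            expect_true(all(diff(cur$right$ehh) <= 1e-15))
        }
    }
})

test_that("EHH at the core uses allele-defined groups", {
    # 4 haplotypes, alleles 0,0,1,1 at the core: EHH = (1+1)/6
    hap <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    sites <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(100, 200), width = 1))
    p <- HaplotypePanel(hap, sites)
    cur <- fullCurve(p, 1)
    expect_equal(cur$right$ehh[1], 2 / 6)
    # extended groups {2,1,1} at site 2 would need identical pairs: here
    # groups are {(0,0)},{(0,1)},{(1,0)},{(1,1)} -> EHH = 0
    expect_equal(cur$right$ehh[2], 0)
    # a {2,1,1} grouping gives C(2,2)/C(4,2) = 1/6
    hap2 <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 0L))
    p2 <- HaplotypePanel(hap2, sites)
    expect_equal(fullCurve(p2, 1)$right$ehh[2], 1 / 6)
})

test_that("identical haplotypes keep EHH at 1 across the chromosome", {
    hap <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), nrow = 6)
    sites <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(10, 20, 30, 40, 50) * 1000, width = 1))
    p <- HaplotypePanel(hap, sites)
    cur <- ehhAtCore(p, 3)
    expect_equal(cur$left$ehh, c(1, 1, 1))
    expect_equal(cur$right$ehh, c(1, 1, 1))
    expect_equal(unname(cur$truncation), rep("chromosome-end", 2))
    # rectangle integral: 20 kb each side
    expect_equal(ihh(cur), 40000)
})

test_that("iHH interpolates the cutoff crossing linearly", {
    cur <- structure(list(
        core = 0,
        left = data.frame(pos = 0, ehh = 1),
        right = data.frame(pos = c(0, 1000, 2000),
                           ehh = c(1, 0.5, 0.04)),
        truncation = c(left = "chromosome-end", right = "cutoff")),
        class = "EhhCurve")
    got <- ihh(cur, cutoff = 0.05)
    crossing <- 1000 + 1000 * (0.5 - 0.05) / (0.5 - 0.04)
    want <- 750 + (0.5 + 0.05) / 2 * (crossing - 1000)
    expect_equal(got, want)
    expect_equal(got, trapezoidOracle(cur$right$pos, cur$right$ehh, 0.05),
                 tolerance = 1e-4)
})

test_that("doubling inter-site distances doubles iHH", {
    p <- randPanel(8, 10, seed = 7)
    cur <- fullCurve(p, 5)
    stretch <- function(df) data.frame(pos = 2 * df$pos, ehh = df$ehh)
    cur2 <- cur
    cur2$left <- stretch(cur$left); cur2$right <- stretch(cur$right)
    expect_equal(ihh(cur2, cutoff = 0), 2 * ihh(cur, cutoff = 0))
})

test_that("max-gap and cutoff truncation are reported", {
    hap <- matrix(rep(c(0L, 1L, 0L), each = 4), nrow = 4)
    sites <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1000, 2000, 300000), width = 1))
    p <- HaplotypePanel(hap, sites)
    cur <- ehhAtCore(p, 2, maxGap = 200000)
    expect_equal(cur$truncation[["right"]], "max-gap")
    expect_equal(nrow(cur$right), 1L)  # stops before the gap
})

test_that("XP-EHH is zero on identical panels and negates under swap", {
    tgt <- randPanel(8, 40, seed = 31, population = "target")
    ref <- HaplotypePanel(haplotypes(tgt), siteRanges(tgt), "reference")
    raws <- S4Vectors::mcols(xpehhScan(tgt, ref))$raw
    expect_true(all(raws[!is.na(raws)] == 0))

    ref2 <- randPanelLike(tgt, seed = 32, population = "reference")
    f <- S4Vectors::mcols(xpehhScan(tgt, ref2))$raw
    b <- S4Vectors::mcols(xpehhScan(ref2, tgt))$raw
    expect_identical(is.na(f), is.na(b))
    expect_equal(f[!is.na(f)], -b[!is.na(b)])
})

test_that("a fixed target haplotype region yields positive raw XP-EHH", {
    sim <- simulatePanels(SimParams(
        nTarget = 15, nRef = 15, chromLengths = c(chr1 = 1e6),
        driftF = 0.05, seed = 5,
        sweeps = list(SweepSpec("chr1", 4e5, 6e5, carrierFraction = 1,
                                noiseRate = 0))))
    xp <- xpehhScan(sim$target, sim$reference)
    pos <- GenomicRanges::start(xp)
    mid <- pos > 4.5e5 & pos < 5.5e5
    raw <- S4Vectors::mcols(xp)$raw
    expect_true(all(raw[mid & !is.na(raw)] > 0))
})

test_that("xpehhRaw matches the scan at a single core", {
    tgt <- randPanel(8, 30, seed = 41, population = "target")
    ref <- randPanelLike(tgt, seed = 42, population = "reference")
    scan <- xpehhScan(tgt, ref)
    one <- xpehhRaw(tgt, ref, 15)
    expect_equal(one$ihh_target,
                 S4Vectors::mcols(scan)$ihh_target[15])
    expect_equal(one$raw, S4Vectors::mcols(scan)$raw[15])
})

test_that("normalisation gives mean 0 sd 1 over defined scores", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1:3 * 100, width = 1))
    S4Vectors::mcols(gr)$raw <- c(-1, 0, 1)
    norm <- S4Vectors::mcols(normalizeXpehh(gr))$normalized
    expect_equal(norm, c(-1, 0, 1))  # sample sd is already 1
    gr2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1:50 * 100, width = 1))
    S4Vectors::mcols(gr2)$raw <- c(rnorm(48), NA, NA)
    norm2 <- S4Vectors::mcols(normalizeXpehh(gr2))$normalized
    expect_equal(mean(norm2, na.rm = TRUE), 0, tolerance = 1e-12)
    expect_equal(sd(norm2, na.rm = TRUE), 1, tolerance = 1e-12)
    expect_true(all(is.na(norm2[49:50])))
    S4Vectors::mcols(gr)$raw <- rep(2, 3)
    expect_error(normalizeXpehh(gr), "degenerate")
})

test_that("window means average normalised scores per window", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(10000, 20000, 60000), width = 1))
    S4Vectors::mcols(gr)$normalized <- c(2, 4, NA)
    w <- makeWindows(c(chr1 = 1e5))
    wx <- windowMeanXpehh(gr, w)
    mc <- S4Vectors::mcols(wx)
    expect_equal(mc$mean_xpehh[1], 3)
    expect_equal(mc$n_snps[1], 2L)
    expect_true(is.na(mc$mean_xpehh[3]))  # only the undefined score
    expect_equal(mc$n_snps[3], 0L)
})
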