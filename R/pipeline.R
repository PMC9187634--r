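## Run configuration and end-to-end orchestration:
## simulate -> filter -> fst -> xpehh -> scan -> annotate -> pca.

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their standard defaults:
#' 50 kb windows advanced by 25 kb, windows with <= 5 SNPs removed
#' (`min_snps = 6`), top-1% percentile candidate calling, MAF >= 0.05 and
#' call rate >= 0.80 site filters, GATK-style hard-filter thresholds, the
#' 3-SNPs-in-10-bp cluster rule, and XP-EHH pooled-EHH cutoff 0.05 with a
#' 200 kb maximum gap.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `RunConfig`.
#' @export
runConfig <- function(...) {
    cfg <- list(
        vcf = NULL, popmap = NULL, gtf = NULL, outdir = "sweepscan_run",
        target = "target", reference = "reference",
        window_size = 50000, window_step = 25000,
        min_snps = 6, percentile = 0.99,
        maf = 0.05, call_rate = 0.80,
        hard_filters = list(QD = 2, FS = 60, MQ = 40, MQRankSum = -12.5,
                            ReadPosRankSum = -8, SOR = 3),
        cluster_window_bp = 10, cluster_size = 3,
        autosomes = NULL, exclude_chroms = c("X", "chrX"),
        xpehh_cutoff = 0.05, xpehh_max_gap = 200000,
        min_snp_filter_xpehh = TRUE,
        chrom_lengths = NULL,
        pca_k = 10, ld_window_snps = 50, ld_step_snps = 10, ld_r2_max = 0.2,
        seed = 1,
        simulate = NULL)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror [runConfig()]; unspecified keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(runConfig, vals)
}

## YAML-serialisable view of a config (SimParams flattened to a list).
configAsList <- function(config) {
    cfg <- unclass(config)
    if (!is.null(cfg$simulate) && is(cfg$simulate, "SimParams"))
        cfg$simulate <- simParamsToList(cfg$simulate)
    else if (!is.null(cfg$simulate))
        cfg$simulate <- rapply(cfg$simulate, function(x)
            if (is(x, "SweepSpec")) list(chrom = x@chrom, start = x@start,
                                         end = x@end,
                                         carrier_fraction = x@carrierFraction,
                                         noise_rate = x@noiseRate)
            else x, classes = "ANY", how = "replace")
    cfg
}

configHash <- function(config) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(configAsList(config), tmp)
    unname(tools::md5sum(tmp))
}

outputHeader <- function(config) {
    sprintf("# sweepscan %s config=%s",
            as.character(utils::packageVersion("sweepscan")),
            configHash(config))
}

writeTsvWithHeader <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

windowStatsToDf <- function(gr) {
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               as.data.frame(S4Vectors::mcols(gr)),
               stringsAsFactors = FALSE)
}

#' Core two-statistic scan (in memory)
#'
#' Runs both genome scans on one shared window grid: per-site
#' Weir-Cockerham components, window-weighted Fst and ZFst; per-SNP
#' XP-EHH, genome-wide normalisation and window means; min-SNP filtering;
#' percentile candidate calling (ZFst upper tail; XP-EHH upper and lower
#' tails) and the cross-statistic window overlap.
#'
#' @param genotypes filtered [GenotypeTable-class].
#' @param targetPanel,referencePanel filtered [HaplotypePanel-class]
#'   objects aligned to the genotype sites.
#' @param chromLengths named chromosome lengths in bp.
#' @param config a [runConfig()] list.
#' @return list with `windows`, `siteFst`, `fstWindows` (retained, with
#'   `zfst`), `xpehhSites`, `xpehhWindows` (retained), candidate sets
#'   (`fstCand`, `xpehhCand`, `xpehhCandLower`), `overlap`,
#'   `overlapRegions`, and `counts`.
#' @export
sweepScan <- function(genotypes, targetPanel, referencePanel, chromLengths,
                      config = runConfig()) {
    windows <- makeWindows(chromLengths, config$window_size,
                           config$window_step)
    sf <- siteFst(genotypes, population(targetPanel),
                  population(referencePanel))
    wf <- windowFst(sf, windows)
    wfRet <- minSnpFilter(wf, config$min_snps)
    wfRet <- wfRet[!is.na(S4Vectors::mcols(wfRet)$weighted_fst)]
    wfRet <- zfstTransform(wfRet)

    xp <- xpehhScan(targetPanel, referencePanel, config$xpehh_cutoff,
                    config$xpehh_max_gap)
    xp <- normalizeXpehh(xp)
    wx <- windowMeanXpehh(xp, windows)
    wxRet <- if (isTRUE(config$min_snp_filter_xpehh))
        minSnpFilter(wx, config$min_snps)
    else wx
    wxRet <- wxRet[!is.na(S4Vectors::mcols(wxRet)$mean_xpehh)]

    fstCand <- callCandidates(wfRet, "zfst", config$percentile, "upper")
    xpehhCand <- callCandidates(wxRet, "mean_xpehh", config$percentile,
                                "upper")
    xpehhCandLower <- callCandidates(wxRet, "mean_xpehh",
                                     config$percentile, "lower")
    ov <- overlapCandidates(fstCand, xpehhCand)
    list(windows = windows, siteFst = sf,
         fstWindows = wfRet, xpehhSites = xp, xpehhWindows = wxRet,
         fstCand = fstCand, xpehhCand = xpehhCand,
         xpehhCandLower = xpehhCandLower,
         overlap = ov, overlapRegions = mergeAdjacent(ov$shared),
         counts = c(windows_total = length(windows),
                    fst_windows_retained = length(wfRet),
                    xpehh_windows_retained = length(wxRet),
                    n_fst_candidates = length(fstCand),
                    n_xpehh_candidates = length(xpehhCand),
                    n_xpehh_lower_candidates = length(xpehhCandLower),
                    n_overlap = unname(ov$venn["shared"])))
}

#' Apply the post-calling site filters in pipeline order
#'
#' Hard quality filters, then the SNP cluster rule, then the
#' biallelic/MAF/call-rate filters, then autosome restriction. When
#' `config$autosomes` is `NULL`, all chromosomes except
#' `config$exclude_chroms` count as autosomes.
#'
#' @param gt a [GenotypeTable-class].
#' @param config a [runConfig()] list.
#' @return list with `genotypes` (filtered table) and `counts` (sites
#'   surviving each stage).
#' @export
applySiteFilters <- function(gt, config = runConfig()) {
    counts <- c(input = nrow(gt))
    gt <- hardFilterSites(gt, config$hard_filters)
    counts["after_hard_filter"] <- nrow(gt)
    gt <- clusterFilter(gt, config$cluster_window_bp, config$cluster_size)
    counts["after_cluster_filter"] <- nrow(gt)
    gt <- frequencyFilters(gt, config$maf, config$call_rate)
    counts["after_frequency_filters"] <- nrow(gt)
    autosomes <- config$autosomes
    if (is.null(autosomes)) {
        all_chr <- unique(as.character(GenomeInfoDb::seqnames(
            SummarizedExperiment::rowRanges(gt))))
        autosomes <- setdiff(all_chr, config$exclude_chroms)
    }
    gt <- restrictAutosomes(gt, autosomes)
    counts["after_autosome_restriction"] <- nrow(gt)
    list(genotypes = gt, counts = counts)
}

#' Run the whole pipeline and write a run directory
#'
#' Executes simulate (optional) -> read -> filter -> Fst -> XP-EHH ->
#' candidate calling and overlap -> gene annotation (if a GTF is given)
#' -> LD pruning and PCA, writing every intermediate table, BED exports,
#' a Venn-count JSON, a parameter log and a machine-readable run report.
#' Identical configurations produce byte-identical report JSON.
#'
#' @param config a [runConfig()] list. Provide either `vcf` + `popmap`
#'   paths, or a `simulate` entry ([SimParams-class] or a named list of
#'   its arguments) to generate the input first.
#' @return list with `scan` (from [sweepScan()]), `filter`, `pca`,
#'   `annotation` (or `NULL`), `report` and `outdir`.
#' @export
runAll <- function(config = runConfig()) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- outputHeader(config)
    logLines <- c(hdr, yaml::as.yaml(configAsList(config)))

    if (!is.null(config$simulate)) {
        params <- if (is(config$simulate, "SimParams")) config$simulate
                  else do.call(SimParams, config$simulate)
        sim <- simulateToFiles(params, file.path(config$outdir, "sim"))
        config$vcf <- sim$paths$vcf
        config$popmap <- sim$paths$popmap
    }
    if (is.null(config$vcf) || is.null(config$popmap))
        stop("config error: vcf and popmap (or a simulate block) required")

    inp <- readPhasedVcf(config$vcf, config$popmap)
    flt <- applySiteFilters(inp$genotypes, config)
    gt <- flt$genotypes
    panels <- alignPanelsToSites(inp$panels, gt)
    if (!config$target %in% names(panels) ||
        !config$reference %in% names(panels))
        stop("data error: target/reference populations not found in popmap")

    chromLengths <- config$chrom_lengths
    if (is.null(chromLengths)) chromLengths <- inp$chromLengths
    chroms <- unique(as.character(GenomeInfoDb::seqnames(
        SummarizedExperiment::rowRanges(gt))))
    chromLengths <- chromLengths[chroms]
    if (any(is.na(chromLengths)))
        stop("data error: chromosome lengths missing from VCF header; ",
             "set chrom_lengths in the config")

    scan <- sweepScan(gt, panels[[config$target]],
                      panels[[config$reference]], chromLengths, config)

    annotation <- NULL
    if (!is.null(config$gtf)) {
        genes <- readGtfGenes(config$gtf)
        annotation <- list(
            fst = genesInRegions(genes, mergeAdjacent(
                candidateWindows(scan$fstCand))),
            xpehh = genesInRegions(genes, mergeAdjacent(
                candidateWindows(scan$xpehhCand))),
            overlap = genesInRegions(genes, scan$overlapRegions))
    }

    pruned <- ldPrune(gt, config$ld_window_snps, config$ld_step_snps,
                      config$ld_r2_max)
    k <- min(config$pca_k, ncol(gt) - 1L)
    pca <- pcaGenotypes(gt, pruned$kept, k)

    ## ---- outputs ----
    out <- function(f) file.path(config$outdir, f)
    writeTsvWithHeader(windowStatsToDf(scan$fstWindows), out("fst_windows.tsv"), hdr)
    xpdf <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(scan$xpehhSites)),
        pos = GenomicRanges::start(scan$xpehhSites),
        as.data.frame(S4Vectors::mcols(scan$xpehhSites)))
    writeTsvWithHeader(xpdf, out("xpehh_sites.tsv"), hdr)
    writeTsvWithHeader(windowStatsToDf(scan$xpehhWindows),
                       out("xpehh_windows.tsv"), hdr)
    writeTsvWithHeader(windowStatsToDf(candidateWindows(scan$fstCand)),
                       out("fst_candidates.tsv"), hdr)
    writeTsvWithHeader(windowStatsToDf(candidateWindows(scan$xpehhCand)),
                       out("xpehh_candidates.tsv"), hdr)
    writeBed(candidateWindows(scan$fstCand), out("fst_candidates.bed"))
    writeBed(candidateWindows(scan$xpehhCand), out("xpehh_candidates.bed"))
    writeBed(scan$overlap$shared, out("overlap_windows.bed"))
    writeBed(scan$overlapRegions, out("overlap_regions.bed"))
    jsonlite::write_json(as.list(scan$overlap$venn), out("venn.json"),
                         auto_unbox = TRUE, digits = NA)
    coords <- data.frame(sample = rownames(pca$coordinates),
                         population = pca$populations,
                         pca$coordinates)
    writeTsvWithHeader(coords, out("pca_coordinates.tsv"), hdr)
    writeTsvWithHeader(data.frame(component = seq_along(pca$eigenvalues),
                                  eigenvalue = pca$eigenvalues,
                                  var_explained = pca$varExplained),
                       out("pca_eigenvalues.tsv"), hdr)
    if (!is.null(annotation))
        for (m in names(annotation))
            writeTsvWithHeader(annotation[[m]]$assignments,
                               out(sprintf("genes_%s.tsv", m)), hdr)

    report <- list(
        version = as.character(utils::packageVersion("sweepscan")),
        config_hash = configHash(config),
        seed = config$seed,
        site_counts = as.list(flt$counts),
        panel_sites = nSites(panels[[config$target]]),
        window_counts = as.list(scan$counts),
        thresholds = list(
            zfst = threshold(scan$fstCand),
            xpehh_upper = threshold(scan$xpehhCand),
            xpehh_lower = threshold(scan$xpehhCandLower)),
        ld_pruning = list(kept = length(pruned$kept),
                          removed = nrow(pruned$removed)),
        pc1_var_explained = pca$varExplained[1L])
    if (!is.null(annotation))
        report$gene_counts <- lapply(annotation,
                                     function(a) as.list(a$counts))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(c(logLines,
                 sprintf("stage site counts: %s",
                         paste(names(flt$counts), flt$counts, sep = "=",
                               collapse = " "))),
               out("run.log"))
    list(scan = scan, filter = flt, pca = pca, annotation = annotation,
         report = report, outdir = config$outdir)
}

#' Mirror a scan with target and reference swapped
#'
#' Re-runs the pipeline with the two population roles exchanged (output in
#' `<outdir>_mirror` unless overridden). Window Fst is symmetric, so the
#' mirrored Fst windows equal the forward ones, while raw XP-EHH scores
#' negate; lower-tail XP-EHH candidates of the forward run equal the
#' mirrored run's upper-tail candidates.
#'
#' @param config the forward-run [runConfig()] list.
#' @param outdir output directory for the mirrored run.
#' @return the [runAll()] result of the mirrored run.
#' @export
mirrorScan <- function(config, outdir = paste0(config$outdir, "_mirror")) {
    m <- config
    m$target <- config$reference
    m$reference <- config$target
    m$outdir <- outdir
    runAll(m)
}
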