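## Phased-VCF input and post-calling site filters.

#' Read a phased multi-sample VCF and a population map
#'
#' Parses the VCF through `VariantAnnotation::readVcf`, producing a
#' [GenotypeTable-class] of ALT dosages (missing genotypes kept as `NA`,
#' variant-quality INFO annotations QD, FS, MQ, MQRankSum, ReadPosRankSum
#' and SOR captured when present) and one [HaplotypePanel-class] per
#' population. Haplotype panels are built only from biallelic records whose
#' genotypes are all called and phased: records containing a missing
#' genotype are excluded from the panels (complete phased input is the
#' EHH contract), while a called but *unphased* genotype is treated as a
#' contract violation and raises an error naming the record.
#'
#' @param path VCF file (plain or bgzipped).
#' @param popmap either a path to a two-column TSV (`sample_id`,
#'   `population`) or a data.frame with those columns.
#' @return list with `genotypes` (GenotypeTable over all records),
#'   `panels` (named list of HaplotypePanel, one per population, restricted
#'   to fully phased records), and `chromLengths` (named vector from the
#'   VCF contig headers, `NA` where undeclared).
#' @export
readPhasedVcf <- function(path, popmap) {
    if (is.character(popmap))
        popmap <- utils::read.table(popmap, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "population") %in% colnames(popmap)))
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    samples <- colnames(vcf)
    unknown <- setdiff(samples, popmap$sample_id)
    if (length(unknown))
        stop("samples absent from population map: ",
             paste(unknown, collapse = ", "))
    pops <- popmap$population[match(samples, popmap$sample_id)]

    rr <- SummarizedExperiment::rowRanges(vcf)
    sites <- GenomicRanges::granges(rr)
    names(sites) <- NULL
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(altList)
    S4Vectors::mcols(sites)$ref <- as.character(VariantAnnotation::ref(vcf))
    S4Vectors::mcols(sites)$alt <-
        unstrsplit_chr(altList)
    inf <- VariantAnnotation::info(vcf)
    for (field in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR"))
        if (field %in% colnames(inf))
            S4Vectors::mcols(sites)[[field]] <- as.numeric(inf[[field]])

    gtm <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gtm)) stop("VCF has no GT field")
    codes <- gtCodeTable(unique(as.vector(gtm)))
    idx <- match(as.vector(gtm), codes$gt)
    dosage <- matrix(codes$dosage[idx], nrow = nrow(gtm))
    phased <- matrix(codes$phased[idx], nrow = nrow(gtm))
    missing <- matrix(codes$missing[idx], nrow = nrow(gtm))
    a1 <- matrix(codes$a1[idx], nrow = nrow(gtm))
    a2 <- matrix(codes$a2[idx], nrow = nrow(gtm))

    gt <- GenotypeTable(dosage, sites, samples, pops)

    complete <- rowSums(missing) == 0L
    unphasedCalled <- !phased & !missing
    bad <- which(complete & rowSums(unphasedCalled) > 0L)
    if (length(bad))
        stop(sprintf("unphased genotype in record %s:%d; phased input required",
                     as.character(GenomeInfoDb::seqnames(sites))[bad[1L]],
                     GenomicRanges::start(sites)[bad[1L]]))
    panelRows <- complete & nAlt == 1L
    panels <- lapply(split(seq_along(samples), pops), function(cols) {
        hap <- matrix(0L, nrow = 2L * length(cols), ncol = sum(panelRows))
        for (k in seq_along(cols)) {
            hap[2L * k - 1L, ] <- a1[panelRows, cols[k]]
            hap[2L * k, ] <- a2[panelRows, cols[k]]
        }
        HaplotypePanel(hap, sites[panelRows],
                       population = pops[cols[1L]])
    })
    si <- GenomeInfoDb::seqinfo(vcf)
    chromLengths <- stats::setNames(as.numeric(GenomeInfoDb::seqlengths(si)),
                                    GenomeInfoDb::seqnames(si))
    list(genotypes = gt, panels = panels, chromLengths = chromLengths)
}

## Decode the distinct GT strings of a VCF once (dosage, phase, missing,
## and the two allele indices capped at 1 for the binary panel).
gtCodeTable <- function(gts) {
    parts <- strsplit(gts, "[/|]")
    miss <- vapply(parts, function(p) any(p == "." | p == ""), TRUE)
    dose <- ifelse(miss, NA_integer_,
                   vapply(parts, function(p) sum(p != "0"), 0L))
    alle <- function(i) vapply(seq_along(parts), function(j) {
        if (miss[j] || length(parts[[j]]) < i) return(NA_integer_)
        min(1L, as.integer(parts[[j]][i]))
    }, 0L)
    data.frame(gt = gts, dosage = dose, phased = grepl("|", gts, fixed = TRUE),
               missing = miss, a1 = alle(1L), a2 = alle(2L),
               stringsAsFactors = FALSE)
}

unstrsplit_chr <- function(altList) {
    cl <- as(altList, "CharacterList")
    S4Vectors::unstrsplit(cl, sep = ",")
}

siteKey <- function(gr) {
    paste0(as.character(GenomeInfoDb::seqnames(gr)), ":",
           GenomicRanges::start(gr))
}

#' Hard-filter sites on variant-quality annotations
#'
#' Removes SNPs with QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
#' ReadPosRankSum < -8 or SOR > 3 (GATK-style hard thresholds; all strict
#' inequalities, so values exactly at a threshold are retained). A site
#' lacking an annotation is never removed by that annotation's rule.
#'
#' @param gt a [GenotypeTable-class].
#' @param thresholds named list overriding the default cutoffs.
#' @return the filtered `GenotypeTable` (site order preserved).
#' @export
hardFilterSites <- function(gt, thresholds = list(QD = 2, FS = 60, MQ = 40,
                                                  MQRankSum = -12.5,
                                                  ReadPosRankSum = -8,
                                                  SOR = 3)) {
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(gt))
    bad <- rep(FALSE, nrow(gt))
    lowRules <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum")
    for (field in names(thresholds)) {
        if (!field %in% colnames(mc)) next
        v <- mc[[field]]
        hit <- if (field %in% lowRules) v < thresholds[[field]]
               else v > thresholds[[field]]
        bad <- bad | (!is.na(hit) & hit)
    }
    gt[!bad, ]
}

#' Remove clustered SNPs
#'
#' Drops every SNP that belongs to a run of `clusterSize` consecutive SNPs
#' spanning at most `windowBp` on one chromosome (span measured as last
#' position minus first position), the usual 3-SNPs-in-10-bp cluster rule.
#'
#' @param gt a [GenotypeTable-class] with sorted sites.
#' @param windowBp cluster window span in bp.
#' @param clusterSize number of SNPs forming a cluster.
#' @return the filtered `GenotypeTable`.
#' @export
clusterFilter <- function(gt, windowBp = 10, clusterSize = 3) {
    sites <- SummarizedExperiment::rowRanges(gt)
    chrom <- as.character(GenomeInfoDb::seqnames(sites))
    pos <- GenomicRanges::start(sites)
    bad <- rep(FALSE, length(pos))
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        p <- pos[i]
        n <- length(p)
        if (n < clusterSize) next
        first <- seq_len(n - clusterSize + 1L)
        hit <- first[p[first + clusterSize - 1L] - p[first] <= windowBp]
        for (f in hit) bad[i[f:(f + clusterSize - 1L)]] <- TRUE
    }
    gt[!bad, ]
}

#' Biallelic, MAF and call-rate filters
#'
#' Retains sites that are biallelic, have pooled minor allele frequency
#' `>= maf` (computed on non-missing dosages over all samples, both
#' populations pooled) and have genotypes called in at least
#' `callRate` of the individuals. Boundary values are retained. Sites with
#' no called genotype are removed.
#'
#' @param gt a [GenotypeTable-class].
#' @param maf minimum minor allele frequency.
#' @param callRate minimum fraction of genotyped individuals.
#' @return the filtered `GenotypeTable`.
#' @export
frequencyFilters <- function(gt, maf = 0.05, callRate = 0.80) {
    d <- dosages(gt)
    alt <- S4Vectors::mcols(SummarizedExperiment::rowRanges(gt))$alt
    biallelic <- !grepl(",", alt, fixed = TRUE)
    called <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * called)
    mafv <- pmin(p, 1 - p)
    keep <- biallelic & called > 0L & called / ncol(d) >= callRate &
            !is.na(mafv) & mafv >= maf
    gt[keep, ]
}

#' Restrict a genotype table to declared autosomes
#'
#' Drops all sites on chromosomes outside `autosomes` (e.g. chromosome X
#' and unplaced contigs).
#'
#' @param gt a [GenotypeTable-class].
#' @param autosomes character vector of chromosome names to keep.
#' @return the filtered `GenotypeTable`.
#' @export
restrictAutosomes <- function(gt, autosomes) {
    if (length(autosomes) == 0L) stop("autosome list is empty")
    keep <- as.character(GenomeInfoDb::seqnames(
        SummarizedExperiment::rowRanges(gt))) %in% autosomes
    if (!any(keep)) stop("no sites remain after autosome restriction")
    gt[keep, ]
}

#' Subset haplotype panels to the sites of a filtered genotype table
#'
#' Keeps, in each panel, exactly the columns whose (chrom, pos) survive in
#' `gt`, so the panels fed to XP-EHH match the filtered site set.
#'
#' @param panels named list of [HaplotypePanel-class] objects.
#' @param gt the filtered [GenotypeTable-class].
#' @return the subset panel list.
#' @export
alignPanelsToSites <- function(panels, gt) {
    keys <- siteKey(SummarizedExperiment::rowRanges(gt))
    lapply(panels, function(p) {
        j <- which(siteKey(siteRanges(p)) %in% keys)
        p[, j]
    })
}
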