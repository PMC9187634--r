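## EHH decay, iHH integration, raw and normalised XP-EHH, window averaging.

panelChromSplit <- function(panel) {
    chrom <- as.character(GenomeInfoDb::seqnames(siteRanges(panel)))
    split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
}

#' EHH decay curve around a core SNP
#'
#' Extended haplotype homozygosity at extension site x is the probability
#' that two random haplotypes from the panel are identical at every site
#' from the core to x inclusive, `sum_g C(k_g, 2) / C(n, 2)` over the
#' groups of identical extended haplotypes. At the core itself the groups
#' are defined by the core allele. The curve extends site-by-site on each
#' side until its own EHH drops below `cutoff` (that first below-cutoff
#' point is kept so the integrator can interpolate the crossing), an
#' inter-site gap exceeds `maxGap` bp, or the chromosome ends.
#'
#' @param panel a complete [HaplotypePanel-class] (no missing data).
#' @param core site index (column of the panel).
#' @param cutoff EHH level at which extension stops.
#' @param maxGap largest tolerated inter-site gap in bp.
#' @return an object of class `EhhCurve`: list with `core` (bp), `left`
#'   and `right` data frames of (`pos`, `ehh`) starting at the core, and
#'   `truncation` (reason per side: `cutoff`, `max-gap` or
#'   `chromosome-end`).
#' @export
ehhAtCore <- function(panel, core, cutoff = 0.05, maxGap = 200000) {
    if (nHaplotypes(panel) < 2L) stop("need at least 2 haplotypes")
    idx <- panelChromSplit(panel)
    chrom <- as.character(GenomeInfoDb::seqnames(siteRanges(panel)))[core]
    cols <- idx[[chrom]]
    res <- .ehh_curve_cpp(haplotypes(panel)[, cols, drop = FALSE],
                          match(core, cols),
                          as.numeric(GenomicRanges::start(siteRanges(panel))[cols]),
                          cutoff, maxGap)
    structure(list(core = GenomicRanges::start(siteRanges(panel))[core],
                   left = res$left, right = res$right,
                   truncation = stats::setNames(as.character(res$truncation),
                                                c("left", "right"))),
              class = "EhhCurve")
}

#' @export
print.EhhCurve <- function(x, ...) {
    cat(sprintf("EhhCurve at %d bp: %d left / %d right points (%s / %s)\n",
        x$core, nrow(x$left) - 1L, nrow(x$right) - 1L,
        x$truncation[["left"]], x$truncation[["right"]]))
    invisible(x)
}

integrateSide <- function(df, cutoff) {
    if (nrow(df) < 2L || df$ehh[1L] < cutoff) return(0)
    acc <- 0
    for (i in seq_len(nrow(df) - 1L)) {
        d <- abs(df$pos[i + 1L] - df$pos[i])
        if (df$ehh[i + 1L] < cutoff) {
            t <- (df$ehh[i] - cutoff) / (df$ehh[i] - df$ehh[i + 1L])
            acc <- acc + (df$ehh[i] + cutoff) / 2 * d * t
            return(acc)
        }
        acc <- acc + (df$ehh[i] + df$ehh[i + 1L]) / 2 * d
    }
    acc
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curve against physical position,
#' summed over the left and right sides of the core. Where the curve
#' crosses `cutoff`, the boundary is included up to the linearly
#' interpolated crossing point; a single-point curve integrates to 0.
#'
#' @param curve an `EhhCurve` from [ehhAtCore()].
#' @param cutoff EHH level closing the integral.
#' @return the iHH value in bp units.
#' @export
ihh <- function(curve, cutoff = 0.05) {
    integrateSide(curve$left, cutoff) + integrateSide(curve$right, cutoff)
}

#' Per-SNP XP-EHH scan
#'
#' For every site, integrates the target and reference EHH curves over a
#' shared span on each side of the core: extension proceeds while the EHH
#' of the *pooled* panel (target and reference concatenated) stays at or
#' above `cutoff`, and stops at the interpolated cutoff crossing, at an
#' inter-site gap larger than `maxGap`, or at the chromosome end. The raw
#' score is `ln(iHH_target / iHH_reference)`: positive values indicate
#' extended homozygosity (recent selection) in the target population,
#' negative in the reference. Sites where either iHH is 0 get `NA` raw
#' scores and are excluded from normalisation and window means.
#'
#' @param target,reference [HaplotypePanel-class] objects sharing one site
#'   table.
#' @param cutoff pooled-EHH stopping level.
#' @param maxGap largest tolerated inter-site gap in bp.
#' @return a `GRanges` (one range per site) with metadata columns
#'   `ihh_target`, `ihh_ref` and `raw`.
#' @export
xpehhScan <- function(target, reference, cutoff = 0.05, maxGap = 200000) {
    sitesT <- siteRanges(target)
    if (!identical(GenomicRanges::start(sitesT),
                   GenomicRanges::start(siteRanges(reference))))
        stop("panels do not share a site table")
    idx <- panelChromSplit(target)
    ihhT <- numeric(length(sitesT)); ihhR <- numeric(length(sitesT))
    for (cols in idx) {
        res <- .xpehh_ihh_cpp(
            haplotypes(target)[, cols, drop = FALSE],
            haplotypes(reference)[, cols, drop = FALSE],
            as.numeric(GenomicRanges::start(sitesT)[cols]),
            cutoff, maxGap)
        ihhT[cols] <- res$ihh_target
        ihhR[cols] <- res$ihh_ref
    }
    out <- GenomicRanges::granges(sitesT)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        ihh_target = ihhT, ihh_ref = ihhR,
        raw = ifelse(ihhT > 0 & ihhR > 0, log(ihhT) - log(ihhR),
                     NA_real_))
    out
}

#' Raw XP-EHH at a single core SNP
#'
#' @inheritParams xpehhScan
#' @param core site index.
#' @return list with `ihh_target`, `ihh_ref` and `raw`.
#' @export
xpehhRaw <- function(target, reference, core, cutoff = 0.05,
                     maxGap = 200000) {
    idx <- panelChromSplit(target)
    chrom <- as.character(GenomeInfoDb::seqnames(siteRanges(target)))[core]
    cols <- idx[[chrom]]
    res <- .xpehh_ihh_cpp(
        haplotypes(target)[, cols, drop = FALSE],
        haplotypes(reference)[, cols, drop = FALSE],
        as.numeric(GenomicRanges::start(siteRanges(target))[cols]),
        cutoff, maxGap)
    k <- match(core, cols)
    iT <- res$ihh_target[k]; iR <- res$ihh_ref[k]
    list(ihh_target = iT, ihh_ref = iR,
         raw = if (iT > 0 && iR > 0) log(iT) - log(iR) else NA_real_)
}

#' Normalise XP-EHH scores genome-wide
#'
#' Adds `normalized = (raw - mean) / sd` computed over all defined raw
#' scores pooled across chromosomes (a single stratum, no frequency
#' binning), using the sample standard deviation. Undefined raw scores
#' stay `NA`.
#'
#' @param scores `GRanges` from [xpehhScan()].
#' @return the input with an added `normalized` metadata column.
#' @export
normalizeXpehh <- function(scores) {
    raw <- S4Vectors::mcols(scores)$raw
    ok <- !is.na(raw)
    if (sum(ok) < 2L) stop("need at least two defined raw scores")
    s <- stats::sd(raw[ok])
    if (s == 0) stop("degenerate scan: all raw XP-EHH scores are equal")
    S4Vectors::mcols(scores)$normalized <- (raw - mean(raw[ok])) / s
    scores
}

#' Window-average normalised XP-EHH
#'
#' Arithmetic mean of the normalised scores of the SNPs falling in each
#' window (a SNP on the overlap of two windows counts in both); `n_snps`
#' counts the defined scores per window. Windows with no defined score get
#' `NA` and are dropped downstream.
#'
#' @param scores `GRanges` from [normalizeXpehh()].
#' @param windows window `GRanges` from [makeWindows()].
#' @return `windows` with metadata columns `n_snps` and `mean_xpehh`.
#' @export
windowMeanXpehh <- function(scores, windows) {
    norm <- S4Vectors::mcols(scores)$normalized
    if (is.null(norm)) stop("scores lack a 'normalized' column")
    ok <- !is.na(norm)
    hits <- GenomicRanges::findOverlaps(windows, scores[ok])
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tot <- numeric(length(windows))
    nSnp <- integer(length(windows))
    if (length(qi)) {
        sums <- rowsum(cbind(norm[ok][si], 1), qi)
        w <- as.integer(rownames(sums))
        tot[w] <- sums[, 1L]
        nSnp[w] <- as.integer(sums[, 2L])
    }
    out <- windows
    S4Vectors::mcols(out)$n_snps <- nSnp
    S4Vectors::mcols(out)$mean_xpehh <- ifelse(nSnp > 0L, tot / nSnp,
                                               NA_real_)
    out
}
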