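## Sliding-window grid, min-SNP filter, percentile candidate calling,
## cross-statistic overlap, region merging.

#' Build the sliding-window grid
#'
#' Overlapping windows of `size` bp advanced by `step` bp, anchored at the
#' start of each chromosome: internally 0-based half-open
#' `[k*step, k*step + size)` for every `k*step < length`, truncated at the
#' chromosome end; represented as 1-based inclusive `GRanges`. The grid is
#' shared by the Fst and XP-EHH scans so their windows are comparable.
#'
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param size window width in bp.
#' @param step window step in bp (`0 < step <= size`).
#' @return a sorted window `GRanges`.
#' @examples
#' makeWindows(c(chr1 = 1e5))  # 4 windows, last two truncated/short
#' @export
makeWindows <- function(chromLengths, size = 50000, step = 25000) {
    if (size <= 0 || step <= 0 || step > size)
        stop("need 0 < step <= size")
    if (any(is.na(chromLengths)) || any(chromLengths <= 0))
        stop("chromosome lengths must be positive and known")
    if (is.null(names(chromLengths)))
        stop("chromLengths must be named")
    startsL <- lapply(chromLengths, function(len) seq(0, len - 1, by = step))
    starts0 <- unlist(startsL, use.names = FALSE)
    lens <- rep(unname(chromLengths), lengths(startsL))
    GenomicRanges::GRanges(
        rep(names(chromLengths), lengths(startsL)),
        IRanges::IRanges(starts0 + 1, pmin(starts0 + size, lens)),
        seqinfo = GenomeInfoDb::Seqinfo(names(chromLengths),
                                        unname(chromLengths)))
}

#' Drop sparse windows
#'
#' Removes windows containing 5 or fewer SNPs (i.e. keeps `n_snps >=
#' minSnps`, default boundary exactly 6), the usual guard against
#' false-positive calls from poorly covered windows. Apply before
#' Z-standardisation and percentile thresholding.
#'
#' @param windowStats window `GRanges` with an `n_snps` metadata column.
#' @param minSnps smallest retained SNP count.
#' @return the retained windows.
#' @export
minSnpFilter <- function(windowStats, minSnps = 6) {
    n <- S4Vectors::mcols(windowStats)$n_snps
    if (is.null(n)) stop("windowStats lack an 'n_snps' column")
    windowStats[n >= minSnps]
}

#' Call candidate windows beyond a percentile threshold
#'
#' Computes the empirical quantile (linear interpolation between order
#' statistics) of the statistic over all retained windows and returns the
#' windows whose value lies *strictly* above it (`direction = "upper"`,
#' using `percentile`) or strictly below the mirrored quantile
#' (`direction = "lower"`, using `1 - percentile`).
#'
#' @param windowStats window `GRanges` carrying the statistic.
#' @param statistic name of the metadata column to threshold.
#' @param percentile upper-tail percentile (default 0.99, the top 1%).
#' @param direction `"upper"` or `"lower"`.
#' @return a [CandidateSet-class].
#' @export
callCandidates <- function(windowStats, statistic, percentile = 0.99,
                           direction = c("upper", "lower")) {
    direction <- match.arg(direction)
    v <- S4Vectors::mcols(windowStats)[[statistic]]
    if (is.null(v)) stop("no such statistic column: ", statistic)
    if (anyNA(v)) stop("statistic contains NA; drop undefined windows first")
    if (length(v) < 100L)
        warning("fewer than 100 windows: percentile threshold is unstable")
    if (direction == "upper") {
        thr <- unname(stats::quantile(v, percentile, type = 7))
        members <- v > thr
    } else {
        thr <- unname(stats::quantile(v, 1 - percentile, type = 7))
        members <- v < thr
    }
    new("CandidateSet", statistic = statistic, direction = direction,
        threshold = thr, percentile = percentile,
        windows = windowStats[members], nTotal = length(windowStats))
}

#' Overlap two candidate sets
#'
#' Intersects two candidate sets from the same window grid by exact window
#' identity (same chrom, start, end), the cross-method agreement set, and
#' reports the Venn counts.
#'
#' @param setA,setB [CandidateSet-class] objects built on one grid.
#' @return list with `shared` (`GRanges` of windows in both sets),
#'   `aOnly`, `bOnly`, and `venn` (named counts `a_only`, `b_only`,
#'   `shared`).
#' @export
overlapCandidates <- function(setA, setB) {
    wa <- candidateWindows(setA)
    wb <- candidateWindows(setB)
    sla <- GenomeInfoDb::seqlengths(wa)
    slb <- GenomeInfoDb::seqlengths(wb)
    common <- intersect(names(sla), names(slb))
    if (length(common) == 0L && (length(sla) || length(slb)) &&
        length(wa) && length(wb))
        stop("candidate sets come from different window grids")
    if (!identical(sla[common], slb[common]))
        stop("candidate sets come from different window grids")
    keyA <- paste0(GenomeInfoDb::seqnames(wa), ":",
                   GenomicRanges::start(wa), "-", GenomicRanges::end(wa))
    keyB <- paste0(GenomeInfoDb::seqnames(wb), ":",
                   GenomicRanges::start(wb), "-", GenomicRanges::end(wb))
    shared <- wa[keyA %in% keyB]
    list(shared = shared,
         aOnly = wa[!keyA %in% keyB],
         bOnly = wb[!keyB %in% keyA],
         venn = c(a_only = sum(!keyA %in% keyB),
                  b_only = sum(!keyB %in% keyA),
                  shared = sum(keyA %in% keyB)))
}

#' Merge overlapping candidate windows into regions
#'
#' Collapses overlapping or bookended candidate windows on the same
#' chromosome into maximal regions for BED export; the window remains the
#' unit of record for statistics.
#'
#' @param windows candidate window `GRanges`.
#' @return a reduced `GRanges` of maximal regions.
#' @export
mergeAdjacent <- function(windows) {
    GenomicRanges::reduce(GenomicRanges::sort(windows))
}

#' Export a GRanges as a BED file
#'
#' 0-based half-open coordinates, optionally with a score column.
#'
#' @param gr ranges to write.
#' @param path output path.
#' @param score optional numeric vector (4th/5th BED columns get a name
#'   and this score).
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, score = NULL) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    if (!is.null(score)) {
        df$name <- sprintf("w%d", seq_along(gr))
        df$score <- score
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
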