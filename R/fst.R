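## Weir-Cockerham (1984) two-population Fst: per-site variance components,
## windowed ratio-of-sums estimate, genome-wide Z-standardisation.

#' Weir-Cockerham variance components for two populations
#'
#' Computes the per-site variance components of the two-population diploid
#' Weir-Cockerham estimator: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), from the
#' called diploid counts, ALT-allele frequencies and observed heterozygote
#' proportions of each population. The per-site estimate is
#' `theta = a / (a + b + c)`; the windowed "weighted" estimate is the
#' ratio of sums over sites. All inputs are vectorised.
#'
#' @param n1,n2 called diploid counts per population (each >= 2).
#' @param p1,p2 ALT-allele frequencies per population.
#' @param h1,h2 observed heterozygote proportions per population.
#' @return data.frame with columns `a`, `b`, `c`; no clamping is applied,
#'   so negative components (and negative theta) are possible and retained.
#' @examples
#' wcComponents(10, 10, 1, 0, 0, 0)  # fixed difference: a = 0.5, b = c = 0
#' @export
wcComponents <- function(n1, n2, p1, p2, h1, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    data.frame(a = a, b = b, c = cc)
}

#' Per-site Fst components from a genotype table
#'
#' For each site, computes per-population called counts, ALT frequencies
#' and heterozygote proportions from the dosage matrix (missing genotypes
#' reduce the per-site sample size; nothing is imputed), then the
#' Weir-Cockerham components. Sites where either population has fewer than
#' two called diploids are skipped (`NA` components).
#'
#' @param gt a [GenotypeTable-class].
#' @param target,reference population labels naming the two groups.
#' @return a `GRanges` (one range per site) with metadata columns `a`,
#'   `b`, `c` and `theta` (`NA` where `a + b + c == 0`, e.g. monomorphic
#'   sites, which are excluded from window sums).
#' @export
siteFst <- function(gt, target = "target", reference = "reference") {
    pops <- populations(gt)
    if (!all(c(target, reference) %in% pops))
        stop("target/reference labels not found in the genotype table")
    d <- dosages(gt)
    stat <- function(cols) {
        sub <- d[, cols, drop = FALSE]
        called <- rowSums(!is.na(sub))
        list(n = called,
             p = rowSums(sub, na.rm = TRUE) / (2 * called),
             h = rowSums(sub == 1L, na.rm = TRUE) / called)
    }
    s1 <- stat(which(pops == target))
    s2 <- stat(which(pops == reference))
    ok <- s1$n >= 2L & s2$n >= 2L
    comp <- data.frame(a = rep(NA_real_, nrow(d)), b = NA_real_, c = NA_real_)
    if (any(ok))
        comp[ok, ] <- wcComponents(s1$n[ok], s2$n[ok], s1$p[ok], s2$p[ok],
                                   s1$h[ok], s2$h[ok])
    gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(gt))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(comp)
    denom <- comp$a + comp$b + comp$c
    S4Vectors::mcols(gr)$theta <- ifelse(!is.na(denom) & denom != 0,
                                         comp$a / denom, NA_real_)
    gr
}

#' Window-weighted Fst (ratio of sums)
#'
#' Assigns each usable site to every window containing it (windows
#' overlap, so a site typically serves two) and computes the VCFtools-style
#' "weighted" window estimate `sum(a) / sum(a + b + c)` over sites with a
#' defined non-zero denominator; `n_snps` counts those sites. Windows with
#' no usable site get `NA` and are dropped downstream.
#'
#' @param sitesFst output of [siteFst()].
#' @param windows window `GRanges` from [makeWindows()].
#' @return `windows` with metadata columns `n_snps` and `weighted_fst`.
#' @export
windowFst <- function(sitesFst, windows) {
    mc <- S4Vectors::mcols(sitesFst)
    denom <- mc$a + mc$b + mc$c
    usable <- !is.na(denom) & denom != 0
    hits <- GenomicRanges::findOverlaps(windows, sitesFst[usable])
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    aSum <- numeric(length(windows))
    dSum <- numeric(length(windows))
    nSnp <- integer(length(windows))
    if (length(qi)) {
        sums <- rowsum(cbind(mc$a[usable][si], denom[usable][si], 1), qi)
        w <- as.integer(rownames(sums))
        aSum[w] <- sums[, 1L]
        dSum[w] <- sums[, 2L]
        nSnp[w] <- as.integer(sums[, 3L])
    }
    out <- windows
    S4Vectors::mcols(out)$n_snps <- nSnp
    S4Vectors::mcols(out)$weighted_fst <- ifelse(dSum != 0, aSum / dSum,
                                                 NA_real_)
    out
}

#' Z-standardise window Fst genome-wide
#'
#' Adds `zfst = (weighted_fst - mean) / sd` computed over all windows in
#' the input (apply [minSnpFilter()] first: standardisation is meant to run
#' on the retained windows). The sample standard deviation (denominator
#' N - 1) is used.
#'
#' @param windowStats `GRanges` with a `weighted_fst` metadata column and
#'   no missing values.
#' @return the input with an added `zfst` metadata column.
#' @export
zfstTransform <- function(windowStats) {
    v <- S4Vectors::mcols(windowStats)$weighted_fst
    if (anyNA(v))
        stop("weighted_fst contains NA; drop undefined windows first")
    if (length(v) < 2L) stop("need at least two windows to standardise")
    s <- stats::sd(v)
    if (s == 0) stop("degenerate scan: all window Fst values are equal")
    S4Vectors::mcols(windowStats)$zfst <- (v - mean(v)) / s
    windowStats
}
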