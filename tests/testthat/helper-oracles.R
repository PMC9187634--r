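## Independent reference implementations used to cross-check the package.

## Weir & Cockerham (1984) variance components, written in the general
## r-population form with explicit sums (the package's wcComponents is the
## two-population special case, vectorised).
wcOracle <- function(n, p, h) {
    r <- length(n)
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c(a = a, b = b, c = hbar / 2)
}

## EHH by exhaustive enumeration: group haplotypes by their exact string
## from the core to the extension site (inclusive) and count identical
## pairs.
ehhOracle <- function(hap, core, ext) {
    span <- core:ext
    keys <- apply(hap[, span, drop = FALSE], 1L, paste, collapse = "")
    k <- table(keys)
    n <- nrow(hap)
    sum(choose(k, 2)) / choose(n, 2)
}

## Full one-sided EHH curve from the oracle (core point included, groups
## at the core defined by the core allele).
ehhCurveOracle <- function(hap, core, side = c("left", "right")) {
    side <- match.arg(side)
    ext <- if (side == "left") core:1 else core:ncol(hap)
    vapply(ext, function(x) ehhOracle(hap, core, x), 0)
}

## Dense numeric integration of a piecewise-linear curve down to a cutoff.
trapezoidOracle <- function(pos, ehh, cutoff, n = 2e5) {
    if (length(pos) < 2L || ehh[1L] < cutoff) return(0)
    xs <- seq(pos[1L], pos[length(pos)], length.out = n)
    ys <- approx(pos, ehh, xout = xs)$y
    below <- which(ys < cutoff)
    if (length(below)) {
        xs <- xs[seq_len(below[1L])]
        ys <- ys[seq_len(below[1L])]
        ys[length(ys)] <- cutoff
    }
    sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

## Random phased panel on one chromosome.
randPanel <- function(nHap, nSites, seed, population = "pop",
                      chromLen = 1e5) {
    set.seed(seed)
    pos <- sort(sample.int(chromLen, nSites))
    hap <- matrix(rbinom(nHap * nSites, 1L, runif(nSites, 0.1, 0.9)),
                  nrow = nHap, byrow = TRUE)
    if (nHap %% 2L) stop("nHap must be even")
    sites <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(pos, width = 1L),
        seqinfo = GenomeInfoDb::Seqinfo("chr1", chromLen))
    HaplotypePanel(hap, sites, population)
}

## A second random panel on the same site coordinates as `panel`.
randPanelLike <- function(panel, seed, population = "pop") {
    set.seed(seed)
    nHap <- nHaplotypes(panel); nSites <- nSites(panel)
    hap <- matrix(rbinom(nHap * nSites, 1L, runif(nSites, 0.1, 0.9)),
                  nrow = nHap, byrow = TRUE)
    HaplotypePanel(hap, siteRanges(panel), population)
}
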