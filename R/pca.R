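## LD pruning (indep-pairwise style) and PCA of the joint genotype matrix.

#' Prune SNPs in high linkage disequilibrium
#'
#' Within sliding windows of `windowSnps` kept SNPs advanced by
#' `stepSnps`, scans pairs in position order and, whenever the squared
#' Pearson correlation of dosages exceeds `r2Max`, removes the later site
#' of the pair (deterministic greedy rule, earlier site kept). Windows
#' never span chromosomes, correlations use pairwise-complete dosages, and
#' passes repeat until no violating pair remains among kept sites - so the
#' final kept set contains no within-window pair with r-squared above the
#' threshold. Zero-variance sites have undefined correlation and are never
#' removed for LD (they are reported in `flagged`).
#'
#' @param gt a [GenotypeTable-class].
#' @param windowSnps window width in SNPs.
#' @param stepSnps window step in SNPs.
#' @param r2Max largest tolerated squared correlation.
#' @return list with `kept` (site indices into `gt`), `removed`
#'   (data.frame of removed site index and the kept partner that triggered
#'   removal), and `flagged` (zero-variance site indices).
#' @export
ldPrune <- function(gt, windowSnps = 50, stepSnps = 10, r2Max = 0.2) {
    d <- dosages(gt)
    chrom <- as.character(GenomeInfoDb::seqnames(
        SummarizedExperiment::rowRanges(gt)))
    nS <- nrow(d)
    alive <- rep(TRUE, nS)
    vars <- apply(d, 1L, stats::var, na.rm = TRUE)
    flagged <- which(is.na(vars) | vars == 0)
    remIdx <- integer(0); remPartner <- integer(0)
    repeat {
        changed <- FALSE
        for (ch in unique(chrom)) {
            idx <- which(alive & chrom == ch)
            m <- length(idx)
            if (m < 2L) next
            starts <- seq(1L, m, by = stepSnps)
            for (ws in starts) {
                win <- idx[ws:min(ws + windowSnps - 1L, m)]
                win <- win[alive[win]]
                if (length(win) < 2L) next
                cc <- suppressWarnings(
                    stats::cor(t(d[win, , drop = FALSE]),
                               use = "pairwise.complete.obs"))
                r2 <- cc^2
                for (j in seq_along(win)[-1L]) {
                    if (!alive[win[j]]) next
                    for (i in seq_len(j - 1L)) {
                        if (!alive[win[i]]) next
                        v <- r2[i, j]
                        if (!is.na(v) && v > r2Max) {
                            alive[win[j]] <- FALSE
                            remIdx <- c(remIdx, win[j])
                            remPartner <- c(remPartner, win[i])
                            changed <- TRUE
                            break
                        }
                    }
                }
            }
        }
        if (!changed) break
    }
    list(kept = which(alive),
         removed = data.frame(site = remIdx, partner = remPartner),
         flagged = flagged)
}

#' Principal component analysis of the genotype matrix
#'
#' Variance-standardises each site, `g' = (g - 2 p) / sqrt(2 p (1 - p))`
#' with `p` the pooled sample ALT frequency, sets missing entries to 0
#' after centring (mean imputation), forms the sample-by-sample
#' relationship matrix `G' G'^T / M` over the `M` (pruned) sites and
#' eigendecomposes it. Sample coordinates are eigenvectors scaled by the
#' square root of their eigenvalues.
#'
#' @param gt a [GenotypeTable-class].
#' @param kept optional site indices (e.g. `ldPrune(gt)$kept`); default all.
#' @param k number of components to return (`k <` sample count).
#' @return an object of class `PcaResult`: list with `coordinates`
#'   (samples x k matrix), `eigenvalues` (all, non-increasing),
#'   `varExplained`, and `populations`.
#' @export
pcaGenotypes <- function(gt, kept = NULL, k = 10) {
    d <- dosages(gt)
    if (!is.null(kept)) d <- d[kept, , drop = FALSE]
    nSamp <- ncol(d)
    if (nSamp < 2L) stop("need at least 2 samples")
    if (k >= nSamp) stop("k must be smaller than the sample count")
    p <- rowMeans(d, na.rm = TRUE) / 2
    if (any(is.na(p) | p <= 0 | p >= 1))
        stop("monomorphic or uncalled site reached PCA; filter sites first")
    X <- (d - 2 * p) / sqrt(2 * p * (1 - p))
    X[is.na(X)] <- 0
    G <- crossprod(X) / nrow(X)
    eig <- eigen(G, symmetric = TRUE)
    vals <- pmax(eig$values, 0)
    coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(vals[seq_len(k)]), nrow = k)
    rownames(coords) <- colnames(d)
    colnames(coords) <- sprintf("PC%d", seq_len(k))
    structure(list(coordinates = coords, eigenvalues = vals,
                   varExplained = vals / sum(vals),
                   populations = populations(gt)),
              class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
    cat(sprintf("PcaResult: %d samples, %d components (PC1 %.1f%% variance)\n",
        nrow(x$coordinates), ncol(x$coordinates),
        100 * x$varExplained[1L]))
    invisible(x)
}
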