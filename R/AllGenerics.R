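#' @rdname HaplotypePanel-class
#' @param x a `HaplotypePanel`.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GenotypeTable-class
#' @param x a `GenotypeTable`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname CandidateSet-class
#' @param x a `CandidateSet`.
#' @export
setGeneric("candidateWindows", function(x) standardGeneric("candidateWindows"))

#' @rdname CandidateSet-class
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

## ---- HaplotypePanel methods ----

#' @rdname HaplotypePanel-class
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname HaplotypePanel-class
#' @export
setMethod("siteRanges", "HaplotypePanel", function(x) x@sites)

#' @rdname HaplotypePanel-class
#' @export
setMethod("population", "HaplotypePanel", function(x) x@population)

#' @rdname HaplotypePanel-class
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@haplotypes))

#' @rdname HaplotypePanel-class
#' @export
setMethod("nSites", "HaplotypePanel", function(x) ncol(x@haplotypes))

setMethod("show", "HaplotypePanel", function(object) {
    cat(sprintf("HaplotypePanel '%s': %d haplotypes (%d diploids) x %d sites on %d chromosome(s)\n",
        object@population, nrow(object@haplotypes),
        nrow(object@haplotypes) %/% 2L, ncol(object@haplotypes),
        length(unique(as.character(GenomeInfoDb::seqnames(object@sites))))))
})

#' Subset a HaplotypePanel by site index
#'
#' @param x a `HaplotypePanel`.
#' @param i haplotype (row) indices; missing keeps all.
#' @param j site (column) indices; missing keeps all.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@haplotypes))
    if (missing(j)) j <- seq_len(ncol(x@haplotypes))
    HaplotypePanel(x@haplotypes[i, j, drop = FALSE], x@sites[j],
                   x@population)
})

## ---- GenotypeTable methods ----

#' @rdname GenotypeTable-class
#' @export
setMethod("dosages", "GenotypeTable",
    function(x) SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeTable-class
#' @export
setMethod("populations", "GenotypeTable",
    function(x) SummarizedExperiment::colData(x)$population)

#' @rdname GenotypeTable-class
#' @export
setMethod("nSites", "GenotypeTable", function(x) nrow(x))

setMethod("show", "GenotypeTable", function(object) {
    pops <- table(populations(object))
    cat(sprintf("GenotypeTable: %d sites x %d samples (%s)\n",
        nrow(object), ncol(object),
        paste(sprintf("%s: %d", names(pops), pops), collapse = ", ")))
})

## ---- CandidateSet methods ----

#' @rdname CandidateSet-class
#' @export
setMethod("candidateWindows", "CandidateSet", function(x) x@windows)

#' @rdname CandidateSet-class
#' @export
setMethod("threshold", "CandidateSet", function(x) x@threshold)

#' @rdname CandidateSet-class
#' @export
setMethod("length", "CandidateSet", function(x) length(x@windows))

setMethod("show", "CandidateSet", function(object) {
    cat(sprintf(
        "CandidateSet '%s' (%s tail): %d of %d windows %s %.4g (percentile %.3g)\n",
        object@statistic, object@direction, length(object@windows),
        object@nTotal, if (object@direction == "upper") ">" else "<",
        object@threshold, object@percentile))
})

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: %d + %d diploids, %d chromosome(s), F = %.3g, %d founders, %d sweep(s), seed %d\n",
        object@nTarget, object@nRef, length(object@chromLengths),
        object@driftF, object@nFounders, length(object@sweeps),
        object@seed))
})

setMethod("show", "SweepSpec", function(object) {
    cat(sprintf("SweepSpec: %s:%d-%d carrier %.2f noise %.3g\n",
        object@chrom, object@start, object@end, object@carrierFraction,
        object@noiseRate))
})
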