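#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' HaplotypePanel: phased binary haplotypes for one population
#'
#' Container for a phased haplotype matrix (rows = haplotypes, two per
#' diploid sample; columns = biallelic SNP sites coded 0 = REF, 1 = ALT)
#' together with the genomic coordinates of the sites and the population
#' label. This is the substrate of EHH and XP-EHH computation, which
#' requires complete (no missing) phased data.
#'
#' @slot haplotypes integer matrix of 0/1 values, `2 * n_samples` rows.
#' @slot sites a [GenomicRanges::GRanges] of width-1 SNP positions, sorted,
#'   with metadata columns `ref` and `alt`.
#' @slot population single character population label.
#' @export
setClass("HaplotypePanel",
    representation(
        haplotypes = "matrix",
        sites = "GRanges",
        population = "character"
    )
)

setValidity("HaplotypePanel", function(object) {
    msg <- character()
    h <- object@haplotypes
    if (!is.numeric(h) && !is.integer(h))
        msg <- c(msg, "haplotype matrix must be numeric")
    if (nrow(h) %% 2L != 0L)
        msg <- c(msg, "haplotype row count must be even (two per diploid)")
    if (anyNA(h))
        msg <- c(msg, "haplotype matrix must not contain missing values")
    else if (length(h) && !all(h %in% c(0L, 1L)))
        msg <- c(msg, "haplotype values must be 0 or 1")
    if (ncol(h) != length(object@sites))
        msg <- c(msg, "number of haplotype columns must equal number of sites")
    if (length(object@sites)) {
        chr <- as.factor(GenomeInfoDb::seqnames(object@sites))
        o <- order(chr, GenomicRanges::start(object@sites))
        if (!identical(o, seq_along(object@sites)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
    }
    if (length(object@population) != 1L)
        msg <- c(msg, "population must be a single label")
    if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes 0/1 matrix, haplotypes in rows (two per sample),
#'   sites in columns.
#' @param sites `GRanges` of SNP positions (width 1), one per column.
#' @param population population label.
#' @return A [HaplotypePanel-class] object.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' hp <- HaplotypePanel(matrix(0L, 4, 2), sites, "target")
#' nHaplotypes(hp)
#' @export
HaplotypePanel <- function(haplotypes, sites, population = "pop") {
    storage.mode(haplotypes) <- "integer"
    new("HaplotypePanel", haplotypes = haplotypes, sites = sites,
        population = as.character(population))
}

#' GenotypeTable: diploid dosages with site metadata
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]: rows are SNP
#' sites (with `ref`, `alt` and optional variant-quality annotations QD, FS,
#' MQ, MQRankSum, ReadPosRankSum, SOR as `rowRanges` metadata columns),
#' columns are samples with a `population` column in `colData`, and the
#' single assay `"dosage"` holds ALT-allele dosages in {0, 1, 2, NA}. This
#' is the substrate of site filtering, Fst and PCA.
#'
#' @export
setClass("GenotypeTable", contains = "RangedSummarizedExperiment")

setValidity("GenotypeTable", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        v <- d[!is.na(d)]
        if (length(v) && !all(v %in% 0:2))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param dosage sites x samples matrix of ALT dosages in {0,1,2,NA}.
#' @param sites `GRanges` of SNP positions, metadata columns `ref`, `alt`
#'   and optional quality annotations.
#' @param sampleIds character vector of sample names.
#' @param populations character vector of population labels, one per sample.
#' @return A [GenotypeTable-class] object.
#' @export
GenotypeTable <- function(dosage, sites, sampleIds, populations) {
    storage.mode(dosage) <- "integer"
    colnames(dosage) <- sampleIds
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowRanges = sites,
        colData = S4Vectors::DataFrame(
            population = as.character(populations), row.names = sampleIds))
    new("GenotypeTable", se)
}

#' SweepSpec: one injectable hard-sweep interval
#'
#' Describes a hard selective sweep to inject into a simulated target
#' panel: within `[start, end]` (1-based, inclusive), a fraction
#' `carrierFraction` of haplotypes is replaced by one template haplotype
#' drawn from the panel, with per-site flip probability `noiseRate` on the
#' copied alleles.
#'
#' @slot chrom chromosome name.
#' @slot start,end 1-based inclusive interval bounds in bp.
#' @slot carrierFraction fraction of haplotypes carrying the sweep, between 0 and 1.
#' @slot noiseRate per-site allele flip probability on carrier copies.
#' @export
setClass("SweepSpec",
    representation(chrom = "character", start = "numeric", end = "numeric",
                   carrierFraction = "numeric", noiseRate = "numeric"))

setValidity("SweepSpec", function(object) {
    msg <- character()
    if (object@start >= object@end) msg <- c(msg, "start must be < end")
    if (object@carrierFraction < 0 || object@carrierFraction > 1)
        msg <- c(msg, "carrierFraction must lie in [0, 1]")
    if (object@noiseRate < 0 || object@noiseRate > 1)
        msg <- c(msg, "noiseRate must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname SweepSpec-class
#' @param chrom,start,end,carrierFraction,noiseRate see slots.
#' @export
SweepSpec <- function(chrom, start, end, carrierFraction = 0.95,
                      noiseRate = 0) {
    new("SweepSpec", chrom = as.character(chrom), start = as.numeric(start),
        end = as.numeric(end), carrierFraction = carrierFraction,
        noiseRate = noiseRate)
}

#' SimParams: parameters of the two-population haplotype simulator
#'
#' The simulator draws, per site, an ancestral ALT frequency
#' p ~ Uniform(mafFloor, 1 - mafFloor), then population frequencies from the
#' Balding-Nichols Beta distribution with dispersion `driftF` (so expected
#' Weir-Cockerham Fst is approximately `driftF`), builds `nFounders` founder
#' haplotypes per population, and derives sample haplotypes as founder
#' mosaics with switch probability `switchRate` per bp, which generates
#' background linkage disequilibrium with mean haplotype-block length
#' 1/`switchRate`. Hard sweeps from `sweeps` are then injected into the
#' target panel.
#'
#' @slot nTarget,nRef diploid sample counts per population (>= 2).
#' @slot chromLengths named numeric vector of chromosome lengths in bp.
#' @slot snpDensity expected SNPs per bp (positions are a Poisson process).
#' @slot driftF Balding-Nichols differentiation parameter in [0, 1).
#' @slot nFounders founder haplotypes per population.
#' @slot switchRate founder-switch probability per bp (>= 0).
#' @slot sweeps list of [SweepSpec-class] objects.
#' @slot mafFloor lower bound of the ancestral-frequency distribution.
#' @slot seed integer random seed; identical parameters give byte-identical
#'   simulator output.
#' @export
setClass("SimParams",
    representation(nTarget = "integer", nRef = "integer",
                   chromLengths = "numeric", snpDensity = "numeric",
                   driftF = "numeric", nFounders = "integer",
                   switchRate = "numeric", sweeps = "list",
                   mafFloor = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    if (object@nTarget < 2L || object@nRef < 2L)
        msg <- c(msg, "need at least 2 diploids per population")
    if (length(object@chromLengths) == 0L)
        msg <- c(msg, "at least one chromosome is required")
    if (is.null(names(object@chromLengths)) ||
        any(!nzchar(names(object@chromLengths))))
        msg <- c(msg, "chromLengths must be named")
    if (any(object@chromLengths <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (object@driftF < 0 || object@driftF >= 1)
        msg <- c(msg, "driftF must lie in [0, 1)")
    if (object@switchRate < 0) msg <- c(msg, "switchRate must be >= 0")
    if (object@mafFloor < 0 || object@mafFloor >= 0.5)
        msg <- c(msg, "mafFloor must lie in [0, 0.5)")
    for (sw in object@sweeps) {
        if (!is(sw, "SweepSpec")) {
            msg <- c(msg, "sweeps must be a list of SweepSpec objects")
            break
        }
        len <- object@chromLengths[sw@chrom]
        if (is.na(len) || sw@start < 1 || sw@end > len)
            msg <- c(msg, sprintf("sweep interval %s:%d-%d outside chromosome",
                                  sw@chrom, sw@start, sw@end))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname SimParams-class
#' @param nTarget,nRef,chromLengths,snpDensity,driftF,nFounders,switchRate,sweeps,mafFloor,seed
#'   see slots; defaults give the package's standard two-chromosome fixture.
#' @examples
#' sp <- SimParams(nTarget = 10, nRef = 10,
#'                 chromLengths = c(chr1 = 1e6), seed = 1)
#' @export
SimParams <- function(nTarget = 20, nRef = 20,
                      chromLengths = c(chr1 = 5e6, chr2 = 5e6),
                      snpDensity = 5e-4, driftF = 0.05, nFounders = 30,
                      switchRate = 3e-5, sweeps = list(),
                      mafFloor = 0.05, seed = 1L) {
    if (is(sweeps, "SweepSpec")) sweeps <- list(sweeps)
    new("SimParams", nTarget = as.integer(nTarget), nRef = as.integer(nRef),
        chromLengths = chromLengths, snpDensity = snpDensity,
        driftF = driftF, nFounders = as.integer(nFounders),
        switchRate = switchRate, sweeps = sweeps, mafFloor = mafFloor,
        seed = as.integer(seed))
}

#' CandidateSet: windows exceeding a percentile threshold
#'
#' The windows whose statistic value strictly exceeds (direction "upper")
#' or falls strictly below (direction "lower") the empirical percentile
#' threshold computed over all retained windows.
#'
#' @slot statistic name of the statistic ("zfst" or "xpehh").
#' @slot direction "upper" or "lower".
#' @slot threshold realised threshold value.
#' @slot percentile percentile used (e.g. 0.99).
#' @slot windows `GRanges` of member windows with the statistic as a
#'   metadata column.
#' @slot nTotal number of retained windows the threshold was computed over.
#' @export
setClass("CandidateSet",
    representation(statistic = "character", direction = "character",
                   threshold = "numeric", percentile = "numeric",
                   windows = "GRanges", nTotal = "integer"))

setValidity("CandidateSet", function(object) {
    msg <- character()
    if (!object@direction %in% c("upper", "lower"))
        msg <- c(msg, "direction must be 'upper' or 'lower'")
    if (length(msg)) msg else TRUE
})
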