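## Two-population haplotype simulator: Balding-Nichols differentiation,
## founder-mosaic background LD, injectable hard sweeps.

withLocalSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## Founder-mosaic haplotypes for one population on one chromosome.
## Each haplotype copies a founder, switching founder with probability
## switchRate per bp; allele at a site is the current founder's allele.
mosaicHaplotypes <- function(founders, pos, chromLen, nHap, switchRate) {
    S <- length(pos)
    nF <- nrow(founders)
    out <- matrix(0L, nHap, S)
    for (h in seq_len(nHap)) {
        k <- stats::rpois(1L, chromLen * switchRate)
        if (k > 0L) {
            cuts <- sort(stats::runif(k, min = 1, max = chromLen))
            fidx <- sample.int(nF, k + 1L, replace = TRUE)
            seg <- findInterval(pos, cuts) + 1L
        } else {
            fidx <- sample.int(nF, 1L)
            seg <- rep(1L, S)
        }
        out[h, ] <- founders[cbind(fidx[seg], seq_len(S))]
    }
    out
}

#' Simulate two phased population panels with known differentiation
#'
#' Draws per-site ancestral frequencies, Balding-Nichols population
#' frequencies with dispersion `driftF` (expected genome-wide
#' Weir-Cockerham Fst approximately equal to `driftF`), founder haplotypes,
#' and founder-mosaic sample haplotypes (background LD with mean block
#' length `1/switchRate` bp), then injects the hard sweeps listed in
#' `params`. Fully deterministic given `params@seed`.
#'
#' @param params a [SimParams-class] object.
#' @return A list with elements `target` and `reference`
#'   ([HaplotypePanel-class]), `genotypes` ([GenotypeTable-class], samples
#'   ordered target-then-reference), and `truth` (a `SimTruth` list holding
#'   the parameters, sweep intervals as a `GRanges`, the emitted site count
#'   and the per-population drawn allele-frequency table).
#' @examples
#' sim <- simulatePanels(SimParams(nTarget = 5, nRef = 5,
#'     chromLengths = c(chr1 = 2e5), seed = 42))
#' sim$target
#' @export
simulatePanels <- function(params) {
    validObject(params)
    withLocalSeed(params@seed, {
        chroms <- names(params@chromLengths)
        posL <- list(); pTgtL <- list(); pRefL <- list()
        tgtL <- list(); refL <- list()
        nHapT <- 2L * params@nTarget
        nHapR <- 2L * params@nRef
        for (ci in seq_along(chroms)) {
            L <- params@chromLengths[ci]
            n <- stats::rpois(1L, L * params@snpDensity)
            n <- min(n, L)
            if (n == 0L) { posL[[ci]] <- integer(0); next }
            pos <- sort(sample.int(L, n))
            p <- stats::runif(n, params@mafFloor, 1 - params@mafFloor)
            if (params@driftF == 0) {
                pT <- p; pR <- p
            } else {
                Fr <- (1 - params@driftF) / params@driftF
                pT <- stats::rbeta(n, p * Fr, (1 - p) * Fr)
                pR <- stats::rbeta(n, p * Fr, (1 - p) * Fr)
            }
            fT <- matrix(stats::rbinom(params@nFounders * n, 1L, rep(pT, each = params@nFounders)),
                         nrow = params@nFounders)
            fR <- matrix(stats::rbinom(params@nFounders * n, 1L, rep(pR, each = params@nFounders)),
                         nrow = params@nFounders)
            tgtL[[ci]] <- mosaicHaplotypes(fT, pos, L, nHapT, params@switchRate)
            refL[[ci]] <- mosaicHaplotypes(fR, pos, L, nHapR, params@switchRate)
            posL[[ci]] <- pos
            pTgtL[[ci]] <- pT; pRefL[[ci]] <- pR
        }
        nPer <- lengths(posL)
        if (sum(nPer) == 0L) stop("simulation produced no sites")
        keep <- nPer > 0L
        sites <- GenomicRanges::GRanges(
            rep(chroms[keep], nPer[keep]),
            IRanges::IRanges(unlist(posL[keep]), width = 1L),
            seqinfo = GenomeInfoDb::Seqinfo(chroms, params@chromLengths))
        S4Vectors::mcols(sites)$ref <- rep("A", length(sites))
        S4Vectors::mcols(sites)$alt <- rep("G", length(sites))
        tgtHap <- do.call(cbind, tgtL[keep])
        refHap <- do.call(cbind, refL[keep])
        target <- HaplotypePanel(tgtHap, sites, "target")
        reference <- HaplotypePanel(refHap, sites, "reference")
        for (sw in params@sweeps)
            target <- injectSweep(target, sw,
                                  seed = sample.int(.Machine$integer.max, 1L))
        sweepGr <- if (length(params@sweeps)) {
            GenomicRanges::GRanges(
                vapply(params@sweeps, function(s) s@chrom, ""),
                IRanges::IRanges(
                    vapply(params@sweeps, function(s) s@start, 0),
                    vapply(params@sweeps, function(s) s@end, 0)))
        } else GenomicRanges::GRanges()
        genotypes <- panelsToGenotypes(target, reference)
        truth <- structure(list(
            params = params,
            sweepIntervals = sweepGr,
            siteCount = length(sites),
            alleleFreqs = data.frame(
                chrom = as.character(GenomeInfoDb::seqnames(sites)),
                pos = GenomicRanges::start(sites),
                p_target = unlist(pTgtL[keep]),
                p_reference = unlist(pRefL[keep]))),
            class = "SimTruth")
        list(target = target, reference = reference,
             genotypes = genotypes, truth = truth)
    })
}

## Collapse two phased panels sharing a site table into a diploid
## GenotypeTable (samples ordered target-then-reference).
panelsToGenotypes <- function(target, reference) {
    dose <- function(h) h[seq(1L, nrow(h), 2L), , drop = FALSE] +
                        h[seq(2L, nrow(h), 2L), , drop = FALSE]
    dT <- dose(haplotypes(target)); dR <- dose(haplotypes(reference))
    ids <- c(sprintf("tgt%03d", seq_len(nrow(dT))),
             sprintf("ref%03d", seq_len(nrow(dR))))
    GenotypeTable(t(rbind(dT, dR)), siteRanges(target), ids,
                  c(rep(population(target), nrow(dT)),
                    rep(population(reference), nrow(dR))))
}

#' Inject a hard sweep into a haplotype panel
#'
#' Replaces the alleles of `round(carrierFraction * nHaplotypes)` randomly
#' chosen haplotypes, over the sites inside the sweep interval, with the
#' alleles of one template haplotype drawn from among the carriers, then
#' flips each copied allele independently with probability `noiseRate`.
#' Sites outside the interval are untouched, so the panel keeps its
#' coordinates and dimensions.
#'
#' @param panel a [HaplotypePanel-class].
#' @param spec a [SweepSpec-class].
#' @param seed integer seed for carrier/template choice and noise.
#' @return The modified `HaplotypePanel`.
#' @export
injectSweep <- function(panel, spec, seed = 1L) {
    validObject(spec)
    sites <- siteRanges(panel)
    inSweep <- which(as.character(GenomeInfoDb::seqnames(sites)) == spec@chrom &
                     GenomicRanges::start(sites) >= spec@start &
                     GenomicRanges::start(sites) <= spec@end)
    if (length(inSweep) == 0L)
        stop(sprintf("sweep interval %s:%d-%d contains no sites",
                     spec@chrom, spec@start, spec@end))
    nHap <- nHaplotypes(panel)
    nCarrier <- round(spec@carrierFraction * nHap)
    if (nCarrier == 0L) return(panel)
    withLocalSeed(seed, {
        carriers <- sample.int(nHap, nCarrier)
        template <- haplotypes(panel)[sample(carriers, 1L), inSweep]
        h <- haplotypes(panel)
        block <- matrix(rep(template, each = nCarrier), nrow = nCarrier)
        if (spec@noiseRate > 0) {
            flip <- matrix(stats::rbinom(length(block), 1L, spec@noiseRate),
                           nrow = nCarrier)
            block <- (block + flip) %% 2L
        }
        h[carriers, inSweep] <- block
        HaplotypePanel(h, sites, population(panel))
    })
}

#' Write two phased panels as a VCF 4.2 file
#'
#' Emits one biallelic record per shared site, `GT` fields phased with the
#' `|` separator, sample columns ordered target-then-reference, and
#' `##contig` header lines taken from the panels' `seqinfo`. Output is
#' byte-identical for identical inputs.
#'
#' @param target,reference [HaplotypePanel-class] objects sharing one site
#'   table.
#' @param path output file path.
#' @param sampleIds optional character vector of sample names
#'   (target samples first); defaults to `tgt001..., ref001...`.
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(target, reference, path, sampleIds = NULL) {
    sites <- siteRanges(target)
    if (!identical(GenomicRanges::start(sites),
                   GenomicRanges::start(siteRanges(reference))))
        stop("panels do not share a site table")
    pos <- GenomicRanges::start(sites)
    chrom <- as.character(GenomeInfoDb::seqnames(sites))
    o <- order(factor(chrom, levels = unique(chrom)), pos)
    if (!identical(o, seq_along(pos)))
        stop("sites must be sorted before writing")
    nT <- nHaplotypes(target) %/% 2L
    nR <- nHaplotypes(reference) %/% 2L
    if (is.null(sampleIds))
        sampleIds <- c(sprintf("tgt%03d", seq_len(nT)),
                       sprintf("ref%03d", seq_len(nR)))
    hap <- rbind(haplotypes(target), haplotypes(reference))
    odd <- seq(1L, nrow(hap), 2L)
    gt <- matrix(paste0(hap[odd, , drop = FALSE], "|",
                        hap[odd + 1L, , drop = FALSE]), nrow = length(odd))
    si <- GenomeInfoDb::seqinfo(sites)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=sweepscan-simulator",
             sprintf("##contig=<ID=%s,length=%d>",
                     GenomeInfoDb::seqnames(si),
                     GenomeInfoDb::seqlengths(si)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds), collapse = "\t"))
    ref <- S4Vectors::mcols(sites)$ref
    alt <- S4Vectors::mcols(sites)$alt
    if (is.null(ref)) ref <- rep("A", length(sites))
    if (is.null(alt)) alt <- rep("G", length(sites))
    body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    gtLines <- apply(gt, 2L, paste, collapse = "\t")
    writeLines(c(hdr, paste(body, gtLines, sep = "\t")), path)
    invisible(path)
}

#' Write the sample-to-population map
#'
#' Two-column TSV (`sample_id`, `population`) matching the sample order of
#' [writePhasedVcf()].
#'
#' @inheritParams writePhasedVcf
#' @return `path`, invisibly.
#' @export
writePopmap <- function(target, reference, path, sampleIds = NULL) {
    nT <- nHaplotypes(target) %/% 2L
    nR <- nHaplotypes(reference) %/% 2L
    if (is.null(sampleIds))
        sampleIds <- c(sprintf("tgt%03d", seq_len(nT)),
                       sprintf("ref%03d", seq_len(nR)))
    df <- data.frame(sample_id = sampleIds,
                     population = c(rep(population(target), nT),
                                    rep(population(reference), nR)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## Plain-list view of SimParams (YAML/JSON serialisable).
simParamsToList <- function(p) {
    list(n_target = p@nTarget, n_ref = p@nRef,
         chrom_lengths = as.list(p@chromLengths),
         snp_density = p@snpDensity, drift_F = p@driftF,
         n_founders = p@nFounders, switch_rate = p@switchRate,
         maf_floor = p@mafFloor, seed = p@seed,
         sweeps = lapply(p@sweeps, function(s) list(
             chrom = s@chrom, start = s@start, end = s@end,
             carrier_fraction = s@carrierFraction,
             noise_rate = s@noiseRate)))
}

#' Write simulation ground truth
#'
#' Writes the sweep intervals as a 0-based half-open BED file and the
#' simulation parameters as JSON.
#'
#' @param truth the `truth` element returned by [simulatePanels()].
#' @param bedPath path for the sweep-interval BED.
#' @param jsonPath path for the parameter JSON.
#' @return invisibly, a list of the two paths.
#' @export
writeSimTruth <- function(truth, bedPath, jsonPath) {
    gr <- truth$sweepIntervals
    bed <- if (length(gr)) {
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
    } else data.frame(chrom = character(), start = integer(),
                      end = integer())
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    payload <- simParamsToList(truth$params)
    payload$site_count <- truth$siteCount
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(list(bed = bedPath, json = jsonPath))
}

#' Run the simulator and write its standard output files
#'
#' Convenience wrapper writing `sim.vcf`, `popmap.tsv`, `truth.bed` and
#' `params.json` into `dir`.
#'
#' @param params a [SimParams-class].
#' @param dir output directory (created if absent).
#' @return the simulation list from [simulatePanels()], invisibly, with an
#'   added `paths` element.
#' @export
simulateToFiles <- function(params, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulatePanels(params)
    paths <- list(vcf = file.path(dir, "sim.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  bed = file.path(dir, "truth.bed"),
                  json = file.path(dir, "params.json"))
    writePhasedVcf(sim$target, sim$reference, paths$vcf)
    writePopmap(sim$target, sim$reference, paths$popmap)
    writeSimTruth(sim$truth, paths$bed, paths$json)
    sim$paths <- paths
    invisible(sim)
}
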