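## GTF gene models and candidate-region annotation.

#' Read gene features from a GTF file
#'
#' Imports the GTF through `rtracklayer::import` and returns one range per
#' gene id: `gene`-typed features where present, otherwise the envelope
#' (range) of all features sharing a gene id. Duplicate gene-id lines
#' collapse to a single envelope.
#'
#' @param path GTF file path.
#' @return a `GRanges` with metadata columns `gene_id`, `gene_name` and
#'   `biotype` (`NA` where the attribute is absent).
#' @export
readGtfGenes <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- S4Vectors::mcols(gr)
    if ("type" %in% colnames(mc) && any(mc$type == "gene"))
        gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    if (!"gene_id" %in% colnames(mc)) stop("GTF lacks gene_id attributes")
    ids <- mc$gene_id
    keep <- !is.na(ids) & nzchar(ids)
    if (!all(keep)) {
        warning(sum(!keep), " GTF line(s) without gene_id skipped")
        gr <- gr[keep]; ids <- ids[keep]; mc <- S4Vectors::mcols(gr)
    }
    fid <- factor(ids)
    st <- tapply(GenomicRanges::start(gr), fid, min)
    en <- tapply(GenomicRanges::end(gr), fid, max)
    chr <- tapply(as.character(GenomeInfoDb::seqnames(gr)), fid,
                  function(x) x[1L])
    first <- !duplicated(ids)
    ord <- match(levels(fid), ids[first])
    getAttr <- function(name) {
        if (name %in% colnames(mc)) as.character(mc[[name]][first][ord])
        else rep(NA_character_, nlevels(fid))
    }
    biotype <- if ("gene_biotype" %in% colnames(mc)) getAttr("gene_biotype")
               else getAttr("gene_type")
    out <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        gene_id = levels(fid), gene_name = getAttr("gene_name"),
        biotype = biotype)
    names(out) <- NULL
    GenomicRanges::sort(out)
}

#' Assign genes to candidate regions
#'
#' A gene is assigned to a region when their intervals overlap by at least
#' `minOverlap` bp (default 1, i.e. any touch counts). Returns the
#' assignment table, the unique gene list and its protein-coding subset
#' (genes overlapping several regions are counted once in the unique
#' lists).
#'
#' @param genes gene `GRanges` from [readGtfGenes()].
#' @param regions candidate region/window `GRanges`.
#' @param minOverlap minimum overlap in bp.
#' @return list with `assignments` (data.frame of region coordinates and
#'   gene columns), `genes` (unique gene `GRanges`), `proteinCoding`
#'   (subset with biotype `protein_coding`), and `counts`
#'   (`n_genes`, `n_protein_coding`).
#' @export
genesInRegions <- function(genes, regions, minOverlap = 1L) {
    if (length(regions) && length(genes) &&
        !any(as.character(GenomeInfoDb::seqnames(genes)) %in%
             as.character(GenomeInfoDb::seqnames(regions))))
        stop("no chromosome name shared between GTF and regions; ",
             "a chromosome rename map may be needed")
    hits <- GenomicRanges::findOverlaps(genes, regions,
                                        minoverlap = minOverlap)
    gi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    mc <- S4Vectors::mcols(genes)
    assignments <- data.frame(
        region_chrom = as.character(GenomeInfoDb::seqnames(regions))[ri],
        region_start = GenomicRanges::start(regions)[ri],
        region_end = GenomicRanges::end(regions)[ri],
        gene_id = mc$gene_id[gi],
        gene_name = mc$gene_name[gi],
        biotype = mc$biotype[gi],
        stringsAsFactors = FALSE)
    uniq <- genes[sort(unique(gi))]
    pc <- uniq[!is.na(S4Vectors::mcols(uniq)$biotype) &
               S4Vectors::mcols(uniq)$biotype == "protein_coding"]
    list(assignments = assignments, genes = uniq, proteinCoding = pc,
         counts = c(n_genes = length(uniq), n_protein_coding = length(pc)))
}
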