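## In-code fixtures: a tiny hand-written VCF with quality annotations and
## helpers for window/candidate objects.

## Writes a VCF with the given records; each record is a list with pos,
## ref, alt, info (character, e.g. "QD=1.9"), and gts (character vector).
writeToyVcf <- function(records, samples, path = tempfile(fileext = ".vcf"),
                        chrom = "chr1", chromLen = 1e5) {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom, chromLen),
             sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"x\">",
                     c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum",
                       "SOR")),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    body <- vapply(records, function(r) {
        paste(c(chrom, r$pos, ".", r$ref %||% "A", r$alt %||% "G", ".",
                "PASS", r$info %||% ".", "GT", r$gts), collapse = "\t")
    }, "")
    writeLines(c(hdr, body), path)
    path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toyPopmap <- function(samples, pops,
                      path = tempfile(fileext = ".tsv")) {
    write.table(data.frame(sample_id = samples, population = pops),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

## Window GRanges with attached statistic values, on a declared grid.
statWindows <- function(values, nSnps = rep(10L, length(values)),
                        column = "zfst", chromLen = NULL, size = 50000,
                        step = 25000) {
    if (is.null(chromLen)) chromLen <- step * (length(values) + 1)
    w <- makeWindows(c(chr1 = chromLen), size = size, step = step)
    w <- w[seq_along(values)]
    S4Vectors::mcols(w)$n_snps <- nSnps
    S4Vectors::mcols(w)[[column]] <- values
    w
}

candSet <- function(windows, statistic = "zfst", direction = "upper",
                    threshold = 0, nTotal = 100L) {
    new("CandidateSet", statistic = statistic, direction = direction,
        threshold = threshold, percentile = 0.99, windows = windows,
        nTotal = as.integer(nTotal))
}
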